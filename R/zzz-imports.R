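#' @importFrom stats dpois ppois qpois dnbinom pnbinom qnbinom rpois rnbinom
#'   rbinom rnorm runif plogis qlogis qnorm pnorm sd shapiro.test optim
#'   glm.fit poisson binomial coef setNames AIC predict vcov logLik
#' @importFrom utils head read.csv write.csv packageVersion
NULL
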