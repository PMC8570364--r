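# Shared fixtures, built in code.

# brute-force pmf summation up to a generous support bound
pmf_sum <- function(family, zero_prob, mu, r = NULL, y_max = NULL) {
  if (is.null(y_max)) {
    # count-part quantile pushes far enough into the NB tail
    y_max <- if (family %in% c("zinb", "hnb", "nb")) {
      qnbinom(1e-11, size = r, mu = mu, lower.tail = FALSE)
    } else {
      qpois(1e-11, lambda = mu, lower.tail = FALSE)
    } + 20
  }
  sum(dzicount(0:y_max, family, zero_prob = zero_prob, mu = mu, r = r))
}

# independent pointwise negative log-likelihood via the distributions module
nll_oracle <- function(family, theta, data) {
  p_x <- ncol(data$X)
  has_zero <- family %in% c("zip", "zinb", "hurdle_poisson", "hnb")
  p_z <- if (has_zero) ncol(data$Z) else 0
  has_r <- family %in% c("zinb", "hnb", "nb")
  alpha <- theta[seq_len(p_x)]
  beta <- if (p_z > 0) theta[p_x + seq_len(p_z)] else NULL
  r <- if (has_r) exp(theta[p_x + p_z + 1]) else NULL
  mu <- exp(drop(data$X %*% alpha))
  zp <- if (has_zero) plogis(drop(data$Z %*% beta)) else NULL
  -sum(dzicount(data$y, family, zero_prob = zp, mu = mu, r = r, log = TRUE))
}

# small simulated dataset under the shared single-covariate design
sim_fixture <- function(family, n = 300, beta = c(1, -1), alpha = c(1, 0.5),
                        r = 1.2, kind = "normal", seed = 1) {
  set.seed(seed)
  x <- gen_covariate(kind, n)
  r_use <- if (family %in% c("zinb", "hnb", "nb")) r else NULL
  gen_data(family, beta = beta, alpha = alpha, r = r_use, x = x)
}

fam_r <- function(family, r = 1.2) {
  if (family %in% c("zinb", "hnb", "nb")) r else NULL
}
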