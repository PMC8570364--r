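## Zero-deflation analytics: the deflation condition and percentage,
## structural-vs-sampling-zero standardized differences, and the exact
## hurdle <-> zero-inflated parameter mapping.

#' Probability of a sampling zero under a Poisson or NB count distribution
#'
#' `exp(-mu)` for Poisson; `(r / (mu + r))^r` for the negative binomial.
#' This is the chance that an at-risk observation produces a zero purely by
#' sampling, the quantity the zero-deflation condition compares against.
#'
#' @param mu Positive count mean (vectorized).
#' @param r NB dispersion; required for `count_family = "nb"`.
#' @param count_family `"nb"` (default) or `"poisson"`.
#' @return Probabilities in (0, 1).
#' @export
#' @examples
#' sampling_zero_prob(exp(1), r = 1.2)    # ~0.24
#' sampling_zero_prob(exp(-1), r = 1.2)   # ~0.73
sampling_zero_prob <- function(mu, r = NULL, count_family = c("nb", "poisson")) {
  count_family <- match.arg(count_family)
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("'mu' must be positive", call. = FALSE)
  if (count_family == "nb") {
    if (is.null(r) || !is.finite(r) || r <= 0) stop("'r' must be positive for NB", call. = FALSE)
    (r / (mu + r))^r
  } else {
    exp(-mu)
  }
}

#' Is an observation zero-deflated?
#'
#' TRUE exactly when the probability of observing any zero is strictly below
#' the sampling-zero probability of the count part; ties count as not
#' deflated (a measure-zero event for continuous covariates).
#'
#' @param zero_prob Probability of observing a zero (any source), in `[0, 1]`.
#' @param samp_zero_prob Sampling-zero probability `p(0; mu)`, in `[0, 1]`.
#' @return Logical vector.
#' @export
deflation_indicator <- function(zero_prob, samp_zero_prob) {
  if (any(zero_prob < 0 | zero_prob > 1) || any(samp_zero_prob < 0 | samp_zero_prob > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  zero_prob < samp_zero_prob
}

#' Fraction of zero-deflated observations under a hurdle generating process
#'
#' With `logit(p_i) = z_i' beta` and `log(mu_i) = x_i' alpha` (same single
#' covariate in both components), counts the fraction of observations where
#' `expit(beta0 + beta1 x_i) < (r / (exp(alpha0 + alpha1 x_i) + r))^r`
#' (Poisson analogue `exp(-mu_i)` when `r` is `NULL`).
#'
#' @param beta Length-2 zero-component coefficients `(beta0, beta1)`.
#' @param alpha Length-2 count-component coefficients `(alpha0, alpha1)`.
#' @param r NB dispersion, or `NULL` for a Poisson count part.
#' @param x Covariate vector.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' deflation_percentage(c(1, -2), c(1, -2), r = 1.2, x = rep(0, 100))  # 0
deflation_percentage <- function(beta, alpha, r = NULL, x) {
  stopifnot(length(beta) == 2, length(alpha) == 2)
  zero_p <- plogis(beta[1] + beta[2] * x)
  mu <- exp(alpha[1] + alpha[2] * x)
  cf <- if (is.null(r)) "poisson" else "nb"
  sp <- sampling_zero_prob(mu, r = r, count_family = cf)
  mean(deflation_indicator(zero_p, sp))
}

#' Deflation-percentage surface over a grid of slopes
#'
#' Evaluates [deflation_percentage()] over every `(beta1, alpha1)` pair of the
#' supplied grids on a single simulated covariate draw, reproducing the
#' surfaces that map where a hurdle generating process is zero-deflated.
#'
#' @param beta1_grid,alpha1_grid Numeric grids for the two slopes.
#' @param beta0,alpha0 Intercepts (default 1, the zero-inflated regime).
#' @param r NB dispersion (default 1.2).
#' @param covariate `"bernoulli"` or `"normal"`.
#' @param n Covariate length (default 300).
#' @param seed Seed for the covariate draw.
#' @param prob Bernoulli success probability (default 0.5).
#' @return `data.frame` with columns `beta1`, `alpha1`, `percentage`.
#' @export
deflation_surface <- function(beta1_grid, alpha1_grid, beta0 = 1, alpha0 = 1,
                              r = 1.2, covariate = c("bernoulli", "normal"),
                              n = 300, seed = 1, prob = 0.5) {
  covariate <- match.arg(covariate)
  stopifnot(all(is.finite(beta1_grid)), all(is.finite(alpha1_grid)))
  x <- gen_covariate(covariate, n, seed = seed, prob = prob)
  grid <- expand.grid(beta1 = beta1_grid, alpha1 = alpha1_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$percentage <- mapply(function(b1, a1) {
    deflation_percentage(c(beta0, b1), c(alpha0, a1), r = r, x = x)
  }, grid$beta1, grid$alpha1)
  grid
}

#' Standardized difference between two probabilities
#'
#' `d = (p1 - p2) / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2)`, the scale-free
#' contrast between the probability of a structural zero and the probability
#' of a sampling zero at the same covariate value.
#'
#' @param p1,p2 Probabilities in (0, 1); values at exactly 0 or 1 give an
#'   infinite or undefined `d` and raise an error when both are degenerate
#'   and equal (0/0).
#' @return Numeric vector of standardized differences.
#' @export
#' @examples
#' standardized_difference(0.731059, 0.241700)  # ~1.123
standardized_difference <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1) || any(p2 < 0 | p2 > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  denom2 <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  if (any(denom2 == 0 & p1 == p2)) {
    stop("standardized difference is 0/0 when both probabilities are equal ",
         "and degenerate (0 or 1)", call. = FALSE)
  }
  (p1 - p2) / sqrt(denom2)
}

#' Summaries of the structural-vs-sampling-zero discrepancy
#'
#' Reports the arithmetic mean of the standardized differences `d_i` (the
#' surface quantity), together with two exceedance summaries at significance
#' level `level`: the fraction of points with
#' `|d_i| > z_level * sigma(d_i)` where `sigma(d) = sqrt(2 + d^2/4)`, and the
#' mean of `|d_i|` over those exceeding points (0 when none exceed).  Both
#' exceedance readings are reported because the criterion can be read either
#' as a proportion or as a conditional mean; the plain `mean_d` is the
#' default summary.
#'
#' @param d Vector of finite standardized differences.
#' @param level Significance level (default 0.05); `z_level` is the upper
#'   `level` standard-normal quantile.
#' @return List with `mean_d`, `exceedance_fraction`, `exceedance_mean`.
#' @export
discrepancy_summary <- function(d, level = 0.05) {
  if (length(d) == 0) stop("empty 'd'", call. = FALSE)
  if (any(!is.finite(d))) stop("'d' must be finite", call. = FALSE)
  z <- qnorm(1 - level)
  sigma_d <- sqrt(2 + d^2 / 4)
  exceeds <- abs(d) > z * sigma_d
  list(mean_d = mean(d),
       exceedance_fraction = mean(exceeds),
       exceedance_mean = if (any(exceeds)) mean(abs(d[exceeds])) else 0)
}

#' Per-observation deflation report for a hurdle generating process
#'
#' Combines the zero probability `expit(z_i' beta)`, the sampling-zero
#' probability, the deflation indicator and percentage, and the standardized
#' differences with their summaries into one object.
#'
#' @inheritParams deflation_percentage
#' @param level Significance level for the exceedance summaries.
#' @return Object of class `"deflation_report"`.
#' @export
deflation_report <- function(beta, alpha, r = NULL, x, level = 0.05) {
  stopifnot(length(beta) == 2, length(alpha) == 2)
  zero_p <- plogis(beta[1] + beta[2] * x)
  mu <- exp(alpha[1] + alpha[2] * x)
  cf <- if (is.null(r)) "poisson" else "nb"
  sp <- sampling_zero_prob(mu, r = r, count_family = cf)
  deflated <- deflation_indicator(zero_p, sp)
  d <- standardized_difference(zero_p, sp)
  s <- discrepancy_summary(d, level = level)
  structure(list(zero_prob = zero_p, sampling_zero_prob = sp,
                 deflated = deflated, percentage = mean(deflated),
                 d = d, mean_d = s$mean_d,
                 exceedance_fraction = s$exceedance_fraction,
                 exceedance_mean = s$exceedance_mean),
            class = "deflation_report")
}

#' @export
print.deflation_report <- function(x, ...) {
  cat(sprintf("Deflation report: n = %d | deflated %.1f%% | mean d = %.4f\n",
              length(x$deflated), 100 * x$percentage, x$mean_d))
  cat(sprintf("  exceedance fraction %.4f | exceedance mean %.4f\n",
              x$exceedance_fraction, x$exceedance_mean))
  invisible(x)
}

#' Represent a hurdle model as a zero-inflated model
#'
#' Wherever a hurdle model is zero-inflated, equating the total zero
#' probabilities gives the structural-zero probability of the equivalent ZI
#' model: `pi_i = (p_i - p(0; mu_i)) / (1 - p(0; mu_i))`.  For a single
#' binary covariate the mapped zero-component coefficients follow as
#' `beta*_0 = logit(pi)` at `x = 0` and `beta*_1 = logit(pi)` at `x = 1`
#' minus `beta*_0`.  The count components coincide.  At covariate levels
#' where the hurdle model is zero-deflated (`p_i < p(0; mu_i)`) no ZI
#' representation exists; those points are flagged `NA`.
#'
#' @param beta Length-2 hurdle zero-component coefficients.
#' @param alpha Length-2 count-component coefficients.
#' @param r NB dispersion (`NULL` for a Poisson count part).
#' @param count_family `"nb"` or `"poisson"`.
#' @param x Covariate levels at which to evaluate the pointwise mapping;
#'   defaults to the binary levels `c(0, 1)`.
#' @return Object of class `"zi_mapped_params"`: list with `beta_star`
#'   (length-2, only when `x` is exactly `c(0, 1)`), `pi_star` (pointwise
#'   structural-zero probabilities, `NA` where deflated), `valid` (logical),
#'   and the inputs.
#' @export
#' @examples
#' hurdle_to_zi(c(1, 1), c(1, 1), r = 1.2)   # beta* = (0.599, 1.288)
hurdle_to_zi <- function(beta, alpha, r = NULL,
                         count_family = c("nb", "poisson"), x = c(0, 1)) {
  count_family <- match.arg(count_family)
  stopifnot(length(beta) == 2, length(alpha) == 2)
  p  <- plogis(beta[1] + beta[2] * x)
  mu <- exp(alpha[1] + alpha[2] * x)
  p0 <- sampling_zero_prob(mu, r = r, count_family = count_family)
  pi_star <- (p - p0) / (1 - p0)
  valid <- pi_star >= -1e-12       # tolerate rounding at pi exactly 0
  pi_star[valid] <- pmax(pi_star[valid], 0)
  pi_star[!valid] <- NA_real_
  beta_star <- NULL
  if (length(x) == 2 && all(x == c(0, 1)) && all(valid)) {
    b0 <- qlogis(pi_star[1])
    beta_star <- c(b0, qlogis(pi_star[2]) - b0)
    names(beta_star) <- c("beta_star_0", "beta_star_1")
  }
  structure(list(beta_star = beta_star, pi_star = pi_star, valid = valid,
                 x = x, beta = beta, alpha = alpha, r = r,
                 count_family = count_family),
            class = "zi_mapped_params")
}

#' @export
print.zi_mapped_params <- function(x, ...) {
  cat("Hurdle -> ZI mapping (", x$count_family, " count part)\n", sep = "")
  if (!is.null(x$beta_star)) {
    cat(sprintf("  beta*_0 = %.4f, beta*_1 = %.4f\n",
                x$beta_star[1], x$beta_star[2]))
  }
  if (any(!x$valid)) {
    cat("  zero-deflated at x =", paste(x$x[!x$valid], collapse = ", "),
        "- no ZI representation there\n")
  }
  invisible(x)
}

#' Zero probabilities of the hurdle representation of a ZI model
#'
#' The inverse direction of [hurdle_to_zi()]: a ZI model with structural-zero
#' probabilities `pi_i` has total zero probability
#' `p_i = pi_i + (1 - pi_i) p(0; mu_i)`, which is the zero mass of the
#' equivalent hurdle model.  Always `>= p(0; mu_i)` — a ZI model can never be
#' zero-deflated.
#'
#' @param beta_star Length-2 ZI zero-component coefficients.
#' @param alpha Length-2 count-component coefficients.
#' @param r NB dispersion (`NULL` for Poisson).
#' @param count_family `"nb"` or `"poisson"`.
#' @param x Covariate levels.
#' @return Numeric vector of hurdle zero probabilities `p_i`.
#' @export
zi_to_hurdle <- function(beta_star, alpha, r = NULL,
                         count_family = c("nb", "poisson"), x = c(0, 1)) {
  count_family <- match.arg(count_family)
  stopifnot(length(beta_star) == 2, length(alpha) == 2)
  pi_ <- plogis(beta_star[1] + beta_star[2] * x)
  mu  <- exp(alpha[1] + alpha[2] * x)
  p0  <- sampling_zero_prob(mu, r = r, count_family = count_family)
  pi_ + (1 - pi_) * p0
}
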