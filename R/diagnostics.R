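## Randomized quantile residuals, Shapiro-Wilk adequacy testing, and
## non-nested model comparison (Vuong statistic, AIC differences).

#' Randomized quantile residuals for a fitted count model
#'
#' For each observation the randomized lower-tail probability
#' `F(y_i - 1) + u_i * pmf(y_i)` (with `F(-1) = 0`) is mapped through the
#' standard-normal quantile function.  `u_i` is uniform on the half-open
#' interval (0, 1], implemented as `1 - runif(n)`; setting every `u_i = 1`
#' recovers the non-randomized upper-cell quantile residual.  Under a
#' correctly specified model the residuals are i.i.d. standard normal.
#'
#' Tail probabilities are clamped to `[1e-10, 1 - 1e-10]` before the normal
#' quantile so gross misfit produces large finite residuals rather than
#' infinities; the number of clamped values is reported, and a non-trivial
#' clamp count is itself a misfit signal.
#'
#' @param fit A [zicount_fit()] object (its fitted per-observation parameters
#'   are used), or `NULL` when `family`/`zero_prob`/`mu`/`r` are supplied
#'   directly (e.g. true-parameter residuals in calibration studies).
#' @param data A [zicount_data()] object; defaults to the fit's training data.
#' @param seed Integer seed for the uniform randomization (required for
#'   reproducibility).
#' @param family,zero_prob,mu,r Direct parameter interface used when `fit` is
#'   `NULL`.
#' @param u Optional vector of fixed randomization values in (0, 1]
#'   (overrides `seed`; mainly for the deterministic `u = 1` endpoint).
#' @return Object of class `"zih_rqr"`: list with `residuals`, `seed`,
#'   `n_clamped`.
#' @export
#' @examples
#' set.seed(7)
#' d <- gen_data("zip", beta = c(1, 0), alpha = c(1, 0), x = rnorm(200))
#' f <- zicount_fit("zip", d)
#' r <- rqr(f, seed = 1)
#' sw_pvalue(r)
rqr <- function(fit = NULL, data = NULL, seed = NULL,
                family = NULL, zero_prob = NULL, mu = NULL, r = NULL,
                u = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "zicount_fit"))
    if (is.null(data)) data <- fit$data
    if (data$n != fit$data$n) stop("fit/data length mismatch", call. = FALSE)
    family <- fit$family
    zero_prob <- fit$fitted_zero_prob
    mu <- fit$fitted_mu
    r <- if (!is.null(fit$log_r)) exp(fit$log_r) else NULL
    y <- data$y
  } else {
    if (is.null(family) || is.null(mu) || is.null(data)) {
      stop("supply either 'fit' or ('family', parameters, 'data')", call. = FALSE)
    }
    y <- data$y
  }
  n <- length(y)
  if (is.null(u)) {
    if (is.null(seed)) stop("an explicit 'seed' (or fixed 'u') is required", call. = FALSE)
    set.seed(seed)
    u <- 1 - runif(n)          # uniform on (0, 1]
  } else {
    u <- rep_len(u, n)
    if (any(u <= 0 | u > 1)) stop("'u' must lie in (0, 1]", call. = FALSE)
  }
  F_lower <- pzicount(y - 1, family, zero_prob = zero_prob, mu = mu, r = r)
  p_y     <- dzicount(y, family, zero_prob = zero_prob, mu = mu, r = r)
  tail_p <- F_lower + u * p_y
  clamped <- tail_p < 1e-10 | tail_p > 1 - 1e-10
  tail_p <- pmin(pmax(tail_p, 1e-10), 1 - 1e-10)
  structure(list(residuals = qnorm(tail_p), seed = seed,
                 n_clamped = sum(clamped)),
            class = "zih_rqr")
}

#' @export
print.zih_rqr <- function(x, ...) {
  cat("Randomized quantile residuals: n =", length(x$residuals),
      "| clamped tails:", x$n_clamped, "\n")
  print(summary(x$residuals))
  invisible(x)
}

#' Shapiro-Wilk normality p-value for randomized quantile residuals
#'
#' Thin wrapper around [stats::shapiro.test()] enforcing its validity range
#' 3 <= n <= 5000; longer residual vectors should be subsampled by the caller.
#' Under a correctly specified model the p-value is approximately uniform, so
#' rejection at the 5% level should occur for about 5% of replicates.
#'
#' @param residuals A `"zih_rqr"` object or plain numeric vector.
#' @return P-value in `[0, 1]`.
#' @export
sw_pvalue <- function(residuals) {
  x <- if (inherits(residuals, "zih_rqr")) residuals$residuals else as.numeric(residuals)
  n <- length(x)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000; subsample longer residual vectors",
         call. = FALSE)
  }
  shapiro.test(x)$p.value
}

#' Vuong test between two non-nested fits of the same data
#'
#' Computes the pointwise log-likelihood differences
#' `rho_i = log f_A(y_i) - log f_B(y_i)` at the two maximum-likelihood fits
#' and the statistic `V = sqrt(n) * mean(rho) / sd(rho)` (sample standard
#' deviation, n - 1 denominator).  Under equivalence V is asymptotically
#' standard normal; `V > 1.96` favours the first model, `V < -1.96` the
#' second.  No AIC/BIC correction is applied.
#'
#' @param fitA,fitB Two [zicount_fit()] objects fitted to the same data.
#' @param data Shared data; defaults to `fitA$data`.
#' @param level Significance level for the preference call (default 0.05).
#' @return Object of class `"zih_vuong"`: list with `V`, `p_value` (two-sided)
#'   and `preferred` in `{"first", "second", "equivalent"}`.
#' @export
vuong_test <- function(fitA, fitB, data = NULL, level = 0.05) {
  stopifnot(inherits(fitA, "zicount_fit"), inherits(fitB, "zicount_fit"))
  if (is.null(data)) data <- fitA$data
  n <- data$n
  if (fitB$data$n != n) stop("fits must share the same data (n differs)", call. = FALSE)
  rho <- .pointwise_loglik(fitA, data) - .pointwise_loglik(fitB, data)
  s <- sd(rho)
  if (!is.finite(s) || s < 1e-12) {
    stop("degenerate Vuong comparison: pointwise likelihoods are identical",
         call. = FALSE)
  }
  V <- sqrt(n) * mean(rho) / s
  crit <- qnorm(1 - level / 2)
  preferred <- if (V > crit) "first" else if (V < -crit) "second" else "equivalent"
  structure(list(V = V, p_value = 2 * pnorm(-abs(V)), preferred = preferred,
                 n = n, level = level),
            class = "zih_vuong")
}

#' @export
print.zih_vuong <- function(x, ...) {
  cat(sprintf("Vuong test: V = %.4f, two-sided p = %.4g (n = %d)\n",
              x$V, x$p_value, x$n))
  cat("  preferred:", x$preferred, "at level", x$level, "\n")
  invisible(x)
}

#' AIC difference between a misspecified and the true (or reference) model
#'
#' `delta_aic = AIC(wrong) - AIC(true)`.  Differences above 4 are
#' conventionally treated as a material difference in fit.
#'
#' @param fit_wrong,fit_true Two `zicount_fit` objects on the same data.
#' @return Numeric scalar.
#' @export
delta_aic <- function(fit_wrong, fit_true) {
  stopifnot(inherits(fit_wrong, "zicount_fit"), inherits(fit_true, "zicount_fit"))
  fit_wrong$aic - fit_true$aic
}
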