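#' @keywords internal
"_PACKAGE"

## Family tags ---------------------------------------------------------------

.ZIH_FAMILIES <- c("zip", "zinb", "hurdle_poisson", "hnb", "poisson", "nb")
.NB_FAMILIES  <- c("zinb", "hnb", "nb")
.ZI_FAMILIES  <- c("zip", "zinb")
.HURDLE_FAMILIES <- c("hurdle_poisson", "hnb")

#' Model family tags
#'
#' The six count-model families supported throughout the package:
#' `"zip"` and `"zinb"` (zero-inflated Poisson / negative binomial, a mixture
#' of a point mass at zero and an untruncated count distribution), `"hurdle_poisson"`
#' and `"hnb"` (hurdle models: a Bernoulli zero process plus a zero-truncated
#' count distribution for the positives), and the plain `"poisson"` and `"nb"`
#' baselines.
#'
#' @return Character vector of the six family tags.
#' @export
#' @examples
#' zih_families()
zih_families <- function() .ZIH_FAMILIES

.match_family <- function(family) {
  match.arg(family, .ZIH_FAMILIES)
}

.family_has_zero_part <- function(family) {
  family %in% c(.ZI_FAMILIES, .HURDLE_FAMILIES)
}

.family_count_part <- function(family) {
  if (family %in% .NB_FAMILIES) "nb" else "poisson"
}

## Parameter validation -------------------------------------------------------

.check_params <- function(family, zero_prob, mu, r) {
  if (.family_has_zero_part(family)) {
    if (is.null(zero_prob) || any(!is.finite(zero_prob)) ||
        any(zero_prob < 0) || any(zero_prob > 1)) {
      stop("'zero_prob' must lie in [0, 1] for family '", family, "'",
           call. = FALSE)
    }
  }
  if (is.null(mu) || any(!is.finite(mu)) || any(mu <= 0)) {
    stop("'mu' must be positive and finite", call. = FALSE)
  }
  if (family %in% .NB_FAMILIES) {
    if (is.null(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
      stop("NB-family '", family, "' requires a single positive dispersion 'r'",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

.check_counts <- function(y) {
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y))) {
    stop("'y' must contain non-negative integers", call. = FALSE)
  }
  invisible(TRUE)
}

## Count-part kernels (untruncated Poisson / NB) ------------------------------

.count_logpmf <- function(y, mu, r, count_family) {
  if (count_family == "poisson") dpois(y, lambda = mu, log = TRUE)
  else dnbinom(y, size = r, mu = mu, log = TRUE)
}

.count_cdf <- function(q, mu, r, count_family) {
  if (count_family == "poisson") ppois(q, lambda = mu)
  else pnbinom(q, size = r, mu = mu)
}

.count_quantile <- function(p, mu, r, count_family) {
  if (count_family == "poisson") qpois(p, lambda = mu)
  else qnbinom(p, size = r, mu = mu)
}

## log(1 - exp(x)) for x <= 0, stable near both ends
.log1mexp <- function(x) {
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}

## log(a + b) from log a, log b
.logspace_add <- function(la, lb) {
  m <- pmax(la, lb)
  out <- m + log(exp(la - m) + exp(lb - m))
  out[la == -Inf & lb == -Inf] <- -Inf
  out
}

## Probability mass function ---------------------------------------------------

#' Probability mass function for zero-inflated and hurdle count families
#'
#' Evaluates the pmf of a ZIP, ZINB, hurdle-Poisson, hurdle-NB, Poisson or NB
#' distribution.  Zero-inflated families place mass
#' `zero_prob + (1 - zero_prob) * p(0; mu)` at zero and
#' `(1 - zero_prob) * p(y; mu)` elsewhere; hurdle families place mass
#' `zero_prob` at zero exactly, with the positive counts following the
#' zero-truncated count distribution scaled by `1 - zero_prob`.
#' All evaluation happens in log space (log-gamma kernels) so large counts and
#' extreme means do not underflow.
#'
#' @param x Vector of non-negative integer counts.
#' @param family One of [zih_families()].
#' @param zero_prob Zero-component probability: the structural-zero mixing
#'   probability `pi` for ZI families, the zero mass `p` for hurdle families.
#'   Ignored for `"poisson"`/`"nb"`. Scalar or vector recycled against `x`.
#' @param mu Count-component mean (untruncated), positive. Recycled.
#' @param r NB dispersion ("size"; variance `mu + mu^2/r`), required for the
#'   NB-based families, shared across observations.
#' @param log Return log-probabilities?
#' @return Numeric vector of (log-)probabilities.
#' @seealso [pzicount()], [rzicount()], [zicount_moments()]
#' @export
#' @examples
#' dzicount(0, "zinb", zero_prob = 0, mu = exp(1), r = 1.2)  # ~0.24
#' dzicount(0:5, "hurdle_poisson", zero_prob = 0.37, mu = 5)
dzicount <- function(x, family, zero_prob = NULL, mu, r = NULL, log = FALSE) {
  family <- .match_family(family)
  .check_counts(x)
  .check_params(family, zero_prob, mu, r)
  n <- max(length(x), length(zero_prob), length(mu))
  y  <- rep_len(x, n)
  mu <- rep_len(mu, n)
  cf <- .family_count_part(family)
  lc <- .count_logpmf(y, mu, r, cf)

  if (family %in% c("poisson", "nb")) {
    lp <- lc
  } else if (family %in% .ZI_FAMILIES) {
    pi_ <- rep_len(zero_prob, n)
    lpi  <- log(pi_)
    l1mp <- log1p(-pi_)
    lp0  <- .count_logpmf(0, mu, r, cf)
    lp <- ifelse(y == 0L, .logspace_add(lpi, l1mp + lp0), l1mp + lc)
  } else { # hurdle
    p_ <- rep_len(zero_prob, n)
    lp0 <- .count_logpmf(0, mu, r, cf)
    if (any(-expm1(lp0) < 1e-12)) {
      stop("hurdle truncation denominator 1 - p(0; mu) below 1e-12; ",
           "'mu' too close to 0", call. = FALSE)
    }
    lp <- ifelse(y == 0L, log(p_), log1p(-p_) + lc - .log1mexp(lp0))
  }
  if (log) lp else exp(lp)
}

## Cumulative distribution -----------------------------------------------------

#' Cumulative distribution function for zero-inflated and hurdle families
#'
#' Closed-form mixture CDFs: for ZI families
#' `F(q) = pi + (1 - pi) F_c(q)`; for hurdle families
#' `F(q) = p + (1 - p) (F_c(q) - F_c(0)) / (1 - F_c(0))`, with `F_c` the
#' untruncated Poisson/NB CDF.  `q` may be any real; values below 0 give 0.
#'
#' @inheritParams dzicount
#' @param q Vector of quantiles (floored to integers as usual for counts).
#' @return Numeric vector of lower-tail probabilities.
#' @export
#' @examples
#' pzicount(0, "zip", zero_prob = 0.5, mu = 1)  # 0.5 + 0.5*exp(-1)
pzicount <- function(q, family, zero_prob = NULL, mu, r = NULL) {
  family <- .match_family(family)
  .check_params(family, zero_prob, mu, r)
  n <- max(length(q), length(zero_prob), length(mu))
  q  <- rep_len(q, n)
  mu <- rep_len(mu, n)
  cf <- .family_count_part(family)
  Fc <- .count_cdf(pmax(floor(q), -1), mu, r, cf)

  if (family %in% c("poisson", "nb")) {
    out <- Fc
  } else if (family %in% .ZI_FAMILIES) {
    pi_ <- rep_len(zero_prob, n)
    out <- ifelse(q < 0, 0, pi_ + (1 - pi_) * Fc)
  } else {
    p_ <- rep_len(zero_prob, n)
    p0 <- exp(.count_logpmf(0, mu, r, cf))
    if (any(1 - p0 < 1e-12)) {
      stop("hurdle truncation denominator 1 - p(0; mu) below 1e-12", call. = FALSE)
    }
    out <- ifelse(q < 0, 0, p_ + (1 - p_) * (Fc - p0) / (1 - p0))
  }
  pmin(pmax(out, 0), 1)
}

## Moments ---------------------------------------------------------------------

#' Mean and variance of a zero-inflated or hurdle count distribution
#'
#' ZI families use the closed forms `E = (1 - pi) mu` and
#' `Var = (1 - pi) mu (1 + mu pi)` (ZIP) or
#' `Var = (1 - pi) mu (1 + mu/r + pi mu)` (ZINB).  Hurdle families use the
#' conditional-moment identity `E[g(Y) | Y > 0] = E[g(Y)] / (1 - p0)` applied
#' to the untruncated first two moments.
#'
#' @inheritParams dzicount
#' @return List with numeric components `mean` and `variance` (vectors if the
#'   parameters are vectors).
#' @export
#' @examples
#' zicount_moments("zip", zero_prob = 0.4, mu = 2)  # mean 1.2, var 2.16
zicount_moments <- function(family, zero_prob = NULL, mu, r = NULL) {
  family <- .match_family(family)
  .check_params(family, zero_prob, mu, r)
  cf <- .family_count_part(family)
  m2_untrunc <- if (cf == "poisson") mu + mu^2 else mu + mu^2 + mu^2 / r

  if (family %in% c("poisson", "nb")) {
    mean_ <- mu
    var_  <- m2_untrunc - mu^2
  } else if (family %in% .ZI_FAMILIES) {
    pi_ <- zero_prob
    mean_ <- (1 - pi_) * mu
    var_ <- if (cf == "poisson") (1 - pi_) * mu * (1 + mu * pi_)
            else (1 - pi_) * mu * (1 + mu / r + pi_ * mu)
  } else {
    p_ <- zero_prob
    p0 <- exp(.count_logpmf(0, mu, r, cf))
    if (any(1 - p0 < 1e-12)) {
      stop("hurdle truncation denominator below 1e-12", call. = FALSE)
    }
    m1t <- mu / (1 - p0)          # E[Y | Y > 0]
    m2t <- m2_untrunc / (1 - p0)  # E[Y^2 | Y > 0]
    mean_ <- (1 - p_) * m1t
    var_  <- (1 - p_) * m2t - mean_^2
  }
  list(mean = mean_, variance = pmax(var_, 0))
}

## Random generation -----------------------------------------------------------

#' Random counts from zero-inflated and hurdle families
#'
#' ZI families draw a latent Bernoulli(`zero_prob`) structural-zero indicator
#' and, when it is 0, an untruncated Poisson/NB count.  Hurdle families draw
#' Bernoulli(`zero_prob`) for the zero mass and otherwise a zero-truncated
#' count via exact inverse-CDF sampling: a uniform draw is mapped through the
#' conditional quantile `Q(p0 + u (1 - p0))`, which is exact and fast even at
#' small `mu` where rejection sampling stalls.
#'
#' Uses R's global RNG stream; call `set.seed()` (or pass `seed`) for
#' reproducibility.
#'
#' @inheritParams dzicount
#' @param n Number of draws; parameter vectors are recycled to length `n`.
#' @param seed Optional integer seed applied before drawing.
#' @return Integer vector of length `n`.
#' @export
#' @examples
#' rzicount(10, "zip", zero_prob = 1, mu = 5, seed = 1)   # all zeros
#' rzicount(10, "hnb", zero_prob = 0, mu = 2, r = 1.2, seed = 1)  # all >= 1
rzicount <- function(n, family, zero_prob = NULL, mu, r = NULL, seed = NULL) {
  family <- .match_family(family)
  .check_params(family, zero_prob, mu, r)
  if (!is.null(seed)) set.seed(seed)
  mu <- rep_len(mu, n)
  cf <- .family_count_part(family)
  rcount <- function(k, m) {
    if (cf == "poisson") rpois(k, lambda = m) else rnbinom(k, size = r, mu = m)
  }

  if (family %in% c("poisson", "nb")) {
    return(rcount(n, mu))
  }
  zp <- rep_len(zero_prob, n)
  zero <- runif(n) < zp
  out <- integer(n)
  if (family %in% .ZI_FAMILIES) {
    if (any(!zero)) out[!zero] <- rcount(sum(!zero), mu[!zero])
  } else {
    if (any(!zero)) {
      m <- mu[!zero]
      p0 <- exp(.count_logpmf(0, m, r, cf))
      if (any(1 - p0 < 1e-12)) {
        stop("hurdle truncation denominator below 1e-12", call. = FALSE)
      }
      u <- runif(sum(!zero))
      out[!zero] <- .count_quantile(p0 + u * (1 - p0), m, r, cf)
    }
  }
  out
}
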