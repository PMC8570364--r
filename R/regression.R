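## Maximum-likelihood fitting of the six count families.
## Parameter packing order (documented contract): theta = c(alpha, beta, log_r)
##   alpha : count-component coefficients (log link), length p_x
##   beta  : zero-component coefficients (logit link), length p_z
##           (absent for "poisson"/"nb")
##   log_r : log NB dispersion (absent for Poisson-kernel families)

## Linear predictors beyond +-ETA_CAP are treated as boundary (separation /
## zero deflation pushing the logistic component to infinity).
.ETA_CAP <- 30

#' Bundle a count response with its two design matrices
#'
#' Container for the data entering a zero-inflated or hurdle regression:
#' a non-negative integer response `y`, the count-component design matrix `X`
#' (log link) and the zero-component design matrix `Z` (logit link).  Both
#' matrices must carry an intercept as their first column; they may otherwise
#' differ.
#'
#' @param y Non-negative integer response vector.
#' @param X Count-component design matrix (`n x p_x`, first column all ones).
#' @param Z Zero-component design matrix (`n x p_z`, first column all ones);
#'   defaults to `X`.
#' @return Object of class `"zicount_data"`: a list with elements `y`, `X`,
#'   `Z`, `n`.
#' @export
#' @examples
#' x <- rnorm(50)
#' d <- zicount_data(rpois(50, 2), cbind(1, x))
zicount_data <- function(y, X, Z = X) {
  y <- as.numeric(y)
  X <- as.matrix(X); Z <- as.matrix(Z)
  .check_counts(y)
  if (anyNA(X) || anyNA(Z)) stop("design matrices must not contain NA", call. = FALSE)
  n <- length(y)
  if (nrow(X) != n || nrow(Z) != n) stop("row counts of X/Z must match length(y)", call. = FALSE)
  if (any(X[, 1] != 1) || any(Z[, 1] != 1)) {
    stop("first column of X and Z must be an intercept column of ones", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[seq_len(ncol(X))]
  if (is.null(colnames(Z))) colnames(Z) <- c("(Intercept)", paste0("z", seq_len(ncol(Z) - 1)))[seq_len(ncol(Z))]
  structure(list(y = y, X = X, Z = Z, n = n), class = "zicount_data")
}

#' @export
print.zicount_data <- function(x, ...) {
  cat("zicount_data: n =", x$n,
      "| zeros:", sum(x$y == 0),
      sprintf("(%.1f%%)", 100 * mean(x$y == 0)),
      "| p_x =", ncol(x$X), ", p_z =", ncol(x$Z), "\n")
  invisible(x)
}

.theta_layout <- function(family, data) {
  p_x <- ncol(data$X)
  p_z <- if (.family_has_zero_part(family)) ncol(data$Z) else 0L
  has_r <- family %in% .NB_FAMILIES
  list(p_x = p_x, p_z = p_z, has_r = has_r, q = p_x + p_z + as.integer(has_r))
}

.unpack_theta <- function(theta, layout) {
  alpha <- theta[seq_len(layout$p_x)]
  beta  <- if (layout$p_z > 0) theta[layout$p_x + seq_len(layout$p_z)] else NULL
  log_r <- if (layout$has_r) theta[layout$p_x + layout$p_z + 1L] else NULL
  list(alpha = alpha, beta = beta, log_r = log_r)
}

#' Negative log-likelihood of a packed parameter vector
#'
#' Evaluates `-sum(log pmf(y_i))` for any supported family with
#' per-observation `mu_i = exp(x_i' alpha)` and zero-component probability
#' `logit^{-1}(z_i' beta)`.  `theta` packs `c(alpha, beta, log_r)` in that
#' fixed order (beta absent for plain Poisson/NB, `log_r` absent for
#' Poisson-kernel families).  Linear predictors are capped at +-30 so the
#' value stays finite over the whole parameter space.
#'
#' @param family One of [zih_families()].
#' @param theta Packed parameter vector.
#' @param data A [zicount_data()] object.
#' @return Scalar negative log-likelihood.
#' @export
zicount_negloglik <- function(family, theta, data) {
  family <- .match_family(family)
  stopifnot(inherits(data, "zicount_data"))
  if (any(!is.finite(theta))) stop("non-finite theta", call. = FALSE)
  layout <- .theta_layout(family, data)
  if (length(theta) != layout$q) {
    stop("theta has length ", length(theta), ", expected ", layout$q, call. = FALSE)
  }
  par <- .unpack_theta(theta, layout)
  eta_x <- pmin(pmax(drop(data$X %*% par$alpha), -.ETA_CAP), .ETA_CAP)
  mu <- exp(eta_x)
  r <- if (layout$has_r) exp(par$log_r) else NULL
  y <- data$y
  cf <- .family_count_part(family)
  lc <- .count_logpmf(y, mu, r, cf)

  if (family %in% c("poisson", "nb")) return(-sum(lc))

  eta_z <- pmin(pmax(drop(data$Z %*% par$beta), -.ETA_CAP), .ETA_CAP)
  if (family %in% .ZI_FAMILIES) {
    lpi  <- plogis(eta_z, log.p = TRUE)
    l1mp <- plogis(eta_z, lower.tail = FALSE, log.p = TRUE)
    lp0  <- .count_logpmf(0, mu, r, cf)
    ll <- ifelse(y == 0, .logspace_add(lpi, l1mp + lp0), l1mp + lc)
  } else {
    lp   <- plogis(eta_z, log.p = TRUE)
    l1mp <- plogis(eta_z, lower.tail = FALSE, log.p = TRUE)
    lp0  <- .count_logpmf(0, mu, r, cf)
    ll <- ifelse(y == 0, lp, l1mp + lc - .log1mexp(lp0))
  }
  -sum(ll)
}

#' Optimisation settings for [zicount_fit()]
#'
#' @param max_iter Maximum BFGS iterations per start.
#' @param tol Gradient-norm (max abs component) tolerance declaring
#'   convergence at the optimum.
#' @param n_restarts Extra jittered restarts attempted when the first
#'   optimisation fails to converge.
#' @param restart_seed Seed for the restart jitter.
#' @return List of class `"zicount_control"`.
#' @export
zicount_control <- function(max_iter = 500L, tol = 1e-3, n_restarts = 2L,
                            restart_seed = 42L) {
  stopifnot(max_iter >= 1, tol > 0, n_restarts >= 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 n_restarts = as.integer(n_restarts),
                 restart_seed = as.integer(restart_seed)),
            class = "zicount_control")
}

## central-difference gradient of the negative log-likelihood
.num_grad <- function(fn, theta, eps = 1e-6) {
  vapply(seq_along(theta), function(j) {
    h <- eps * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    (fn(tp) - fn(tm)) / (2 * h)
  }, numeric(1))
}

.num_hessian <- function(fn, theta, eps = 1e-4) {
  q <- length(theta)
  H <- matrix(NA_real_, q, q)
  f0 <- fn(theta)
  h <- eps * pmax(1, abs(theta))
  for (i in seq_len(q)) {
    for (j in i:q) {
      tpp <- theta; tpp[i] <- tpp[i] + h[i]; tpp[j] <- tpp[j] + h[j]
      tpm <- theta; tpm[i] <- tpm[i] + h[i]; tpm[j] <- tpm[j] - h[j]
      tmp <- theta; tmp[i] <- tmp[i] - h[i]; tmp[j] <- tmp[j] + h[j]
      tmm <- theta; tmm[i] <- tmm[i] - h[i]; tmm[j] <- tmm[j] - h[j]
      H[i, j] <- H[j, i] <- (fn(tpp) - fn(tpm) - fn(tmp) + fn(tmm)) / (4 * h[i] * h[j])
    }
  }
  H
}

.start_values <- function(family, data, layout) {
  y <- data$y
  ## count part: Poisson GLM on all data (hurdle refits on positives later,
  ## but this start is cheap and points the right way)
  alpha <- tryCatch(
    suppressWarnings(coef(glm.fit(data$X, y, family = poisson()))),
    error = function(e) c(log(mean(y) + 0.1), rep(0, layout$p_x - 1)))
  alpha[!is.finite(alpha)] <- 0
  beta <- NULL
  if (layout$p_z > 0) {
    beta <- tryCatch(
      suppressWarnings(coef(glm.fit(data$Z, as.numeric(y == 0), family = binomial()))),
      error = function(e) c(qlogis(pmin(pmax(mean(y == 0), 0.02), 0.98)),
                            rep(0, layout$p_z - 1)))
    beta[!is.finite(beta)] <- 0
  }
  c(alpha, beta, if (layout$has_r) 0)
}

.optimize_nll <- function(fn, start, control) {
  best <- NULL
  starts <- list(start)
  if (control$n_restarts > 0) {
    set.seed(control$restart_seed)
    for (k in seq_len(control$n_restarts)) {
      starts[[k + 1]] <- start + rnorm(length(start), sd = 0.5)
    }
  }
  for (s in starts) {
    res <- tryCatch(
      optim(s, fn, method = "BFGS",
            control = list(maxit = control$max_iter, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
    g <- .num_grad(fn, best$par)
    if (max(abs(g)) <= control$tol) break
  }
  if (is.null(best)) stop("optimization failed for all starting values", call. = FALSE)
  best
}

#' Fit a zero-inflated, hurdle or plain count regression by maximum likelihood
#'
#' Quasi-Newton (BFGS) maximisation of the log-likelihood on the packed
#' parameter scale `c(alpha, beta, log_r)`.  Hurdle families exploit the exact
#' likelihood factorisation: the zero part is a logistic regression of
#' `1{y = 0}` on `Z` (fitted by IRLS) and the truncated count part is
#' maximised independently on the positive observations.  Starting values come
#' from a logistic fit of the zero indicator and a Poisson fit of the counts.
#'
#' Zero-component separation (including zero-deflated data, which pushes the
#' ZI logistic component towards minus infinity) is detected as any fitted
#' zero-component linear predictor beyond +-30; the fit is then flagged
#' `boundary = TRUE` and reported rather than failing, since its AIC is still
#' a valid comparison target.  Standard errors come from the numerically
#' differentiated Hessian and are unreliable at a boundary.
#'
#' @param family One of [zih_families()].
#' @param data A [zicount_data()] object.
#' @param control A [zicount_control()] list.
#' @return Object of class `"zicount_fit"` with components `family`, `alpha`,
#'   `beta`, `log_r`, `theta`, `loglik`, `q`, `aic`, `converged`, `boundary`,
#'   `se`, `fitted_zero_prob`, `fitted_mu`, and the training `data`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(300)
#' d <- gen_data("zip", beta = c(1, -1), alpha = c(1, 0.5), x = x)
#' f <- zicount_fit("zip", d)
#' coef(f); AIC(f)
zicount_fit <- function(family, data, control = zicount_control()) {
  family <- .match_family(family)
  stopifnot(inherits(data, "zicount_data"), inherits(control, "zicount_control"))
  layout <- .theta_layout(family, data)
  y <- data$y
  if (data$n < layout$q + 1) {
    stop("need n >= ", layout$q + 1, " observations to fit '", family, "'",
         call. = FALSE)
  }

  if (family %in% .HURDLE_FAMILIES && all(y == 0)) {
    stop("all-zero response: the truncated count part of a hurdle model ",
         "cannot be fitted", call. = FALSE)
  }

  if (family %in% .HURDLE_FAMILIES) {
    fit <- .fit_hurdle(family, data, layout, control)
  } else {
    start <- .start_values(family, data, layout)
    fn <- function(th) zicount_negloglik(family, th, data)
    opt <- .optimize_nll(fn, start, control)
    g <- .num_grad(fn, opt$par)
    fit <- list(theta = opt$par, nll = opt$value,
                converged = max(abs(g)) <= control$tol &&
                  opt$value <= fn(start) + 1e-8)
  }

  par <- .unpack_theta(fit$theta, layout)
  eta_x <- drop(data$X %*% par$alpha)
  fitted_mu <- exp(pmin(pmax(eta_x, -.ETA_CAP), .ETA_CAP))
  fitted_zero <- NULL
  boundary <- FALSE
  if (layout$p_z > 0) {
    eta_z <- drop(data$Z %*% par$beta)
    fitted_zero <- plogis(pmin(pmax(eta_z, -.ETA_CAP), .ETA_CAP))
    ## separation at single observations, or a zero component degenerate
    ## everywhere (the likelihood flattens before eta reaches the cap, so the
    ## per-observation rule alone misses global zero deflation)
    boundary <- any(abs(eta_z) > .ETA_CAP) ||
      all(fitted_zero < 1e-6) || all(fitted_zero > 1 - 1e-6)
    ## keep probabilities inside (0,1)
    fitted_zero <- pmin(pmax(fitted_zero, 1e-13), 1 - 1e-13)
  }

  se <- rep(NA_real_, layout$q)
  H <- tryCatch(.num_hessian(function(th) zicount_negloglik(family, th, data),
                             fit$theta),
                error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      se <- ifelse(dv > 0, sqrt(dv), NA_real_)
    }
  }

  loglik <- -fit$nll
  q <- layout$q
  names(par$alpha) <- colnames(data$X)
  if (!is.null(par$beta)) names(par$beta) <- colnames(data$Z)
  structure(list(
    family = family,
    alpha = par$alpha, beta = par$beta, log_r = par$log_r,
    theta = fit$theta, se = se,
    loglik = loglik, q = q, aic = -2 * loglik + 2 * q,
    converged = fit$converged, boundary = boundary,
    fitted_zero_prob = fitted_zero, fitted_mu = fitted_mu,
    data = data, control = control
  ), class = "zicount_fit")
}

## hurdle likelihood factorises: logistic zero part + truncated count part
.fit_hurdle <- function(family, data, layout, control) {
  y <- data$y
  z_ind <- as.numeric(y == 0)
  bin <- suppressWarnings(glm.fit(data$Z, z_ind, family = binomial()))
  beta <- coef(bin)
  beta[!is.finite(beta)] <- 0
  eta_z <- pmin(pmax(drop(data$Z %*% beta), -.ETA_CAP), .ETA_CAP)
  ll_zero <- sum(ifelse(y == 0, plogis(eta_z, log.p = TRUE),
                        plogis(eta_z, lower.tail = FALSE, log.p = TRUE)))

  pos <- y > 0
  cf <- .family_count_part(family)
  has_r <- layout$has_r
  Xp <- data$X[pos, , drop = FALSE]
  yp <- y[pos]
  trunc_nll <- function(th) {
    alpha <- th[seq_len(layout$p_x)]
    r <- if (has_r) exp(th[layout$p_x + 1L]) else NULL
    mu <- exp(pmin(pmax(drop(Xp %*% alpha), -.ETA_CAP), .ETA_CAP))
    lp0 <- .count_logpmf(0, mu, r, cf)
    -sum(.count_logpmf(yp, mu, r, cf) - .log1mexp(lp0))
  }
  a0 <- tryCatch(
    suppressWarnings(coef(glm.fit(Xp, yp, family = poisson()))),
    error = function(e) c(log(mean(yp)), rep(0, layout$p_x - 1)))
  a0[!is.finite(a0)] <- 0
  start <- c(a0, if (has_r) 0)
  opt <- .optimize_nll(trunc_nll, start, control)
  g <- .num_grad(trunc_nll, opt$par)
  theta <- c(opt$par[seq_len(layout$p_x)], beta,
             if (has_r) opt$par[layout$p_x + 1L])
  list(theta = theta, nll = -(ll_zero - opt$value),
       converged = bin$converged && max(abs(g)) <= control$tol)
}

## S3 methods ------------------------------------------------------------------

#' @export
print.zicount_fit <- function(x, ...) {
  cat("Count regression fit, family:", x$family, "\n")
  cat(sprintf("  logLik %.4f | AIC %.4f | q = %d | converged: %s%s\n",
              x$loglik, x$aic, x$q, x$converged,
              if (x$boundary) " | BOUNDARY (zero-component separation)" else ""))
  cat("  count coefficients (log link):\n")
  print(x$alpha)
  if (!is.null(x$beta)) {
    cat("  zero coefficients (logit link):\n")
    print(x$beta)
  }
  if (!is.null(x$log_r)) {
    cat(sprintf("  dispersion r = %.4f (log r = %.4f)\n", exp(x$log_r), x$log_r))
  }
  invisible(x)
}

#' @export
logLik.zicount_fit <- function(object, ...) {
  structure(object$loglik, df = object$q, class = "logLik")
}

#' @export
coef.zicount_fit <- function(object, ...) {
  cf <- c(setNames(object$alpha, paste0("count_", names(object$alpha))),
          if (!is.null(object$beta))
            setNames(object$beta, paste0("zero_", names(object$beta))),
          if (!is.null(object$log_r)) c(log_r = object$log_r))
  cf
}

#' @export
vcov.zicount_fit <- function(object, ...) {
  fn <- function(th) zicount_negloglik(object$family, th, object$data)
  solve(.num_hessian(fn, object$theta))
}

#' AIC for a fitted count model
#'
#' `AIC = -2 logLik + 2 q`, where `q` counts every estimated parameter
#' including `log r` for NB-kernel families.
#'
#' @param object A `zicount_fit`.
#' @param ... Unused.
#' @param k Penalty per parameter (2 for AIC).
#' @return Numeric scalar.
#' @export
AIC.zicount_fit <- function(object, ..., k = 2) {
  -2 * object$loglik + k * object$q
}

#' Predict zero-component probabilities and count means
#'
#' @param object A `zicount_fit`.
#' @param newZ Zero-component design matrix (same columns as training `Z`);
#'   defaults to the training matrix.
#' @param newX Count-component design matrix; defaults to the training matrix.
#' @param ... Unused.
#' @return List with `zero_prob` (`NULL` for plain Poisson/NB) and `mu`.
#' @export
predict.zicount_fit <- function(object, newZ = NULL, newX = NULL, ...) {
  if (is.null(newX)) newX <- object$data$X
  if (is.null(newZ)) newZ <- object$data$Z
  newX <- as.matrix(newX); newZ <- as.matrix(newZ)
  if (ncol(newX) != length(object$alpha)) stop("newX column count mismatch", call. = FALSE)
  mu <- exp(pmin(pmax(drop(newX %*% object$alpha), -.ETA_CAP), .ETA_CAP))
  zp <- NULL
  if (!is.null(object$beta)) {
    if (ncol(newZ) != length(object$beta)) stop("newZ column count mismatch", call. = FALSE)
    zp <- plogis(pmin(pmax(drop(newZ %*% object$beta), -.ETA_CAP), .ETA_CAP))
  }
  list(zero_prob = zp, mu = mu)
}

## per-observation log pmf under a fit (used by Vuong and RQR)
.pointwise_loglik <- function(fit, data = fit$data) {
  dzicount(data$y, fit$family,
           zero_prob = if (is.null(fit$fitted_zero_prob) && !is.null(fit$beta))
             plogis(drop(data$Z %*% fit$beta)) else fit$fitted_zero_prob,
           mu = fit$fitted_mu,
           r = if (!is.null(fit$log_r)) exp(fit$log_r) else NULL,
           log = TRUE)
}
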