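# Maximum-likelihood fitting and the packed-likelihood surface.

test_that("negative log-likelihood matches the pointwise pmf oracle", {
  # closed form: one observation y = 0, intercept-only ZIP at theta = (0, 0)
  d1 <- structure(list(y = 0, X = matrix(1, 1, 1), Z = matrix(1, 1, 1), n = 1L),
                  class = "zicount_data")
  expect_equal(zicount_negloglik("zip", c(0, 0), d1),
               -log(0.5 + 0.5 * exp(-1)), tolerance = 1e-12)

  set.seed(42)
  for (fam in zih_families()) {
    d <- sim_fixture(fam, n = 40, seed = 5)
    p_x <- ncol(d$X)
    p_z <- if (fam %in% c("poisson", "nb")) 0 else ncol(d$Z)
    q <- p_x + p_z + (fam %in% c("zinb", "hnb", "nb"))
    for (k in 1:3) {
      theta <- rnorm(q, sd = 0.5)
      expect_equal(zicount_negloglik(fam, theta, d), nll_oracle(fam, theta, d),
                   tolerance = 1e-10)
    }
  }
  expect_error(zicount_negloglik("zip", c(NA, 0), d1), "non-finite")
})

test_that("hurdle likelihood factorizes into logistic and truncated parts", {
  d <- sim_fixture("hnb", n = 400, beta = c(1, -1), alpha = c(1, 0.5), seed = 8)
  fit <- zicount_fit("hnb", d)
  # zero part equals an independent logistic regression of 1{y == 0}
  glm_fit <- glm(I(d$y == 0) ~ d$X[, 2], family = binomial)
  expect_equal(unname(fit$beta), unname(coef(glm_fit)), tolerance = 1e-5)
  # total loglik = Bernoulli part + truncated-count part
  eta_z <- drop(d$Z %*% fit$beta)
  ll_zero <- sum(ifelse(d$y == 0, plogis(eta_z, log.p = TRUE),
                        plogis(eta_z, lower.tail = FALSE, log.p = TRUE)))
  pos <- d$y > 0
  mu <- exp(drop(d$X[pos, ] %*% fit$alpha))
  r <- exp(fit$log_r)
  ll_trunc <- sum(dnbinom(d$y[pos], size = r, mu = mu, log = TRUE) -
                  log1p(-dnbinom(0, size = r, mu = mu)))
  expect_equal(fit$loglik, ll_zero + ll_trunc, tolerance = 1e-6)
})

test_that("intercept-only Poisson fit recovers the closed-form MLE", {
  set.seed(3)
  y <- rpois(200, 3.7)
  d <- zicount_data(y, matrix(1, 200, 1))
  fit <- zicount_fit("poisson", d)
  expect_equal(unname(fit$alpha), log(mean(y)), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("ZINB fit recovers the generating coefficients", {
  d <- sim_fixture("zinb", n = 5000, beta = c(1, -1), alpha = c(1, 0.5),
                   seed = 31)
  fit <- zicount_fit("zinb", d)
  truth <- c(1, 0.5, 1, -1, log(1.2))   # (alpha, beta, log_r) packing
  expect_true(fit$converged)
  expect_true(all(abs(fit$theta - truth) < 3 * fit$se))
  expect_lt(max(abs(fit$theta - truth)), 0.5)
})

test_that("coefficient estimates tighten as the sample grows", {
  err <- sapply(c(500, 5000), function(n) {
    d <- sim_fixture("zip", n = n, beta = c(1, -1), alpha = c(1, 0.5),
                     seed = 17)
    fit <- zicount_fit("zip", d)
    max(abs(fit$theta - c(1, 0.5, 1, -1)))
  })
  expect_lt(err[2], err[1])
})

test_that("Wald intervals cover the truth at close to nominal rate", {
  reps <- 60
  covered <- matrix(NA, reps, 4)
  for (i in seq_len(reps)) {
    d <- sim_fixture("zip", n = 1000, beta = c(1, -1), alpha = c(1, 0.5),
                     seed = 400 + i)
    fit <- zicount_fit("zip", d)
    truth <- c(1, 0.5, 1, -1)
    covered[i, ] <- abs(fit$theta - truth) <= qnorm(0.975) * fit$se
  }
  expect_gte(min(colMeans(covered)), 0.90)
})

test_that("design-column permutation permutes coefficients, not the fit", {
  set.seed(12)
  x1 <- rnorm(400); x2 <- rbinom(400, 1, 0.5)
  d <- gen_data("zip", beta = c(1, -1), alpha = c(1, 0.5), x = x1)
  X_a <- cbind(1, x1, x2)
  X_b <- cbind(1, x2, x1)
  da <- zicount_data(d$y, X_a, X_a)
  db <- zicount_data(d$y, X_b, X_b)
  fa <- zicount_fit("zip", da)
  fb <- zicount_fit("zip", db)
  expect_equal(fa$loglik, fb$loglik, tolerance = 1e-6)
  expect_equal(unname(fa$alpha[c(1, 3, 2)]), unname(fb$alpha), tolerance = 1e-4)
  expect_equal(unname(fa$beta[c(1, 3, 2)]), unname(fb$beta), tolerance = 1e-4)
})

test_that("AIC counts every estimated parameter", {
  d <- sim_fixture("zinb", n = 300, seed = 9)
  fit <- zicount_fit("zinb", d)
  expect_identical(fit$q, 5L)                       # 2 + 2 + log_r
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 5)
  expect_equal(AIC(fit), fit$aic)
  fit_p <- zicount_fit("poisson", d)
  expect_identical(fit_p$q, 2L)
})

test_that("predict applies the links and reproduces training fits", {
  d <- sim_fixture("zip", n = 300, seed = 10)
  fit <- zicount_fit("zip", d)
  pr <- predict(fit)
  expect_equal(pr$mu, fit$fitted_mu)
  expect_equal(pr$zero_prob, fit$fitted_zero_prob, tolerance = 1e-12)
  # hand-built single rows: logit^{-1}(Z beta), exp(X alpha)
  fit$beta <- c(1, 0); fit$alpha <- c(1, 1)
  one <- predict(fit, newZ = matrix(c(1, 0), 1), newX = matrix(c(1, 1), 1))
  expect_equal(one$zero_prob, plogis(1), tolerance = 1e-12)
  expect_equal(one$mu, exp(2), tolerance = 1e-12)
  expect_error(predict(fit, newX = matrix(1, 2, 3)), "mismatch")
})

test_that("degenerate responses and deflated data are handled as specified", {
  d0 <- zicount_data(rep(0, 30), matrix(1, 30, 1))
  expect_error(zicount_fit("hnb", d0), "all-zero")
  # globally zero-deflated data push the ZI logistic component to the boundary
  set.seed(4)
  d <- gen_data("hurdle_poisson", beta = c(-3, 0), alpha = c(0.3, 0),
                x = rnorm(400))
  fit <- zicount_fit("zip", d)
  expect_true(fit$boundary)
  expect_true(is.finite(fit$aic))
})

test_that("maximized log-likelihoods agree with glmmTMB", {
  skip_if_not_installed("glmmTMB")
  d <- sim_fixture("zinb", n = 300, beta = c(1, -1), alpha = c(1, 0.5),
                   seed = 77)
  df <- data.frame(y = d$y, x = d$X[, 2])
  fit <- zicount_fit("zinb", d)
  tmb <- glmmTMB::glmmTMB(y ~ x, ziformula = ~x, family = glmmTMB::nbinom2,
                          data = df)
  expect_equal(fit$loglik, as.numeric(logLik(tmb)), tolerance = 1e-4)

  dh <- sim_fixture("hnb", n = 300, beta = c(1, -1), alpha = c(1, 0.5),
                    seed = 78)
  dfh <- data.frame(y = dh$y, x = dh$X[, 2])
  fith <- zicount_fit("hnb", dh)
  tmbh <- glmmTMB::glmmTMB(y ~ x, ziformula = ~x,
                           family = glmmTMB::truncated_nbinom2, data = dfh)
  expect_equal(fith$loglik, as.numeric(logLik(tmbh)), tolerance = 1e-4)
})
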