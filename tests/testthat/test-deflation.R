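# Zero-deflation condition, discrepancy measures, hurdle <-> ZI mapping.

test_that("sampling-zero probabilities hit the printed anchors", {
  expect_equal(round(sampling_zero_prob(exp(1), r = 1.2), 2), 0.24)
  expect_equal(round(sampling_zero_prob(exp(-1), r = 1.2), 2), 0.73)
  expect_gt(sampling_zero_prob(1e-8, count_family = "poisson"), 1 - 1e-7)
  expect_error(sampling_zero_prob(-1, r = 1.2), "positive")
  expect_error(sampling_zero_prob(1), "'r'")
})

test_that("deflation indicator is a strict comparison", {
  expect_true(deflation_indicator(0.27, 0.73))
  expect_false(deflation_indicator(0.73, 0.24))
  expect_false(deflation_indicator(0.5, 0.5))   # tie: not deflated
  expect_error(deflation_indicator(1.2, 0.5), "\\[0, 1\\]")
})

test_that("deflation percentage matches the covariate-level analysis", {
  # at x = 0 the zero probability (~0.73) exceeds the sampling-zero
  # probability (~0.24): never deflated
  expect_equal(deflation_percentage(c(1, -2), c(1, -2), r = 1.2,
                                    x = rep(0, 100)), 0)
  # binary covariate: only the x = 1 level is deflated, so the percentage is
  # exactly the fraction of ones
  x <- c(rep(0, 60), rep(1, 40))
  expect_equal(deflation_percentage(c(1, -2), c(1, -2), r = 1.2, x = x), 0.4)
  # standard-normal covariate: deflation iff x above ~0.516 (where the zero
  # and sampling-zero probability curves cross), so ~30% in expectation
  set.seed(1)
  pct <- replicate(400, deflation_percentage(c(1, -2), c(1, -2), r = 1.2,
                                             x = rnorm(300)))
  expect_gt(mean(pct), 0.30)
  f_gap <- function(t) plogis(t) - sampling_zero_prob(exp(t), r = 1.2)
  x_star <- (1 - uniroot(f_gap, c(-0.2, 0))$root) / 2
  expect_equal(mean(pct), pnorm(x_star, lower.tail = FALSE), tolerance = 0.01)
})

test_that("deflation surface has grid shape and the expected corners", {
  surf <- deflation_surface(c(-2, 0, 2), c(-2, 0, 2), covariate = "bernoulli",
                            n = 4000, seed = 2)
  expect_identical(nrow(surf), 9L)
  expect_true(all(surf$percentage >= 0 & surf$percentage <= 1))
  at <- function(b, a) surf$percentage[surf$beta1 == b & surf$alpha1 == a]
  expect_equal(at(-2, -2), 0.5, tolerance = 0.05)  # ~fraction of ones
  expect_identical(at(2, 2), 0)                    # x=1: 0.95 vs 0.09
  # normal covariate at (2, 2): deflated points are those with x below ~-0.5
  x <- gen_covariate("normal", 2000, seed = 3)
  zp <- plogis(1 + 2 * x)
  sp <- sampling_zero_prob(exp(1 + 2 * x), r = 1.2)
  defl <- deflation_indicator(zp, sp)
  cut <- max(x[defl])
  expect_lt(abs(cut - (-0.5)), 0.1)
  # determinism
  expect_identical(surf, deflation_surface(c(-2, 0, 2), c(-2, 0, 2),
                                           covariate = "bernoulli",
                                           n = 4000, seed = 2))
})

test_that("standardized difference: sign, antisymmetry, printed value", {
  expect_identical(standardized_difference(0.3, 0.3), 0)
  expect_equal(standardized_difference(0.731059, 0.241700), 1.1229,
               tolerance = 1e-3)
  expect_equal(standardized_difference(0.2, 0.7),
               -standardized_difference(0.7, 0.2), tolerance = 1e-12)
  expect_error(standardized_difference(1, 1), "0/0")
})

test_that("discrepancy summaries follow the printed exceedance criterion", {
  s0 <- discrepancy_summary(c(0, 0, 0))
  expect_equal(unlist(s0), c(mean_d = 0, exceedance_fraction = 0,
                             exceedance_mean = 0))
  # |20| > 1.645 * sqrt(2 + 100): exceeds at the 5% level
  s1 <- discrepancy_summary(c(20), level = 0.05)
  expect_equal(s1$exceedance_fraction, 1)
  expect_equal(s1$exceedance_mean, 20)
  # d = (1, -1): mean 0, no exceedances (1 < 1.645 * sqrt(2.25))
  s2 <- discrepancy_summary(c(1, -1), level = 0.05)
  expect_equal(s2$mean_d, 0)
  expect_equal(s2$exceedance_fraction, 0)
  expect_error(discrepancy_summary(numeric(0)), "empty")
})

test_that("hurdle -> ZI mapping reproduces the worked example and inverts", {
  m <- hurdle_to_zi(c(1, 1), c(1, 1), r = 1.2, count_family = "nb")
  expect_equal(unname(round(m$beta_star, 3)), c(0.599, 1.288))
  # round trip: mapped ZI model has the same zero probabilities
  p_back <- zi_to_hurdle(m$beta_star, c(1, 1), r = 1.2, count_family = "nb",
                         x = c(0, 1))
  expect_equal(p_back, plogis(c(1, 2)), tolerance = 1e-6)
  # random deflation-free configurations round-trip too
  set.seed(9)
  for (k in 1:10) {
    beta <- c(runif(1, 1, 3), runif(1, 0, 1))
    alpha <- c(runif(1, -0.5, 1), runif(1, -0.5, 0.5))
    m2 <- hurdle_to_zi(beta, alpha, r = 1.2)
    if (is.null(m2$beta_star)) next
    p2 <- zi_to_hurdle(m2$beta_star, alpha, r = 1.2, x = c(0, 1))
    expect_equal(p2, plogis(beta[1] + beta[2] * c(0, 1)), tolerance = 1e-6)
  }
})

test_that("mapping flags zero-deflated covariate levels as invalid", {
  m <- hurdle_to_zi(c(1, -2), c(1, -2), r = 1.2)   # x = 1 is deflated
  expect_true(m$valid[1])
  expect_false(m$valid[2])
  expect_true(is.na(m$pi_star[2]))
  expect_null(m$beta_star)
  # p_i exactly equal to p(0; mu_i) gives pi = 0
  p0 <- sampling_zero_prob(exp(1), r = 1.2)
  m0 <- hurdle_to_zi(c(qlogis(p0), 0), c(1, 0), r = 1.2, x = 0)
  expect_equal(m0$pi_star, 0, tolerance = 1e-12)
})

test_that("a ZI model is never zero-deflated (total zero prob > sampling)", {
  set.seed(4)
  for (k in 1:20) {
    pi_ <- runif(1, 0.01, 0.99); mu <- runif(1, 0.2, 8)
    total <- dzicount(0, "zinb", pi_, mu, r = 1.2)
    expect_gt(total, sampling_zero_prob(mu, r = 1.2))
  }
  x <- rnorm(50)
  p <- zi_to_hurdle(c(-1, 0.5), c(1, 0.3), r = 1.2, x = x)
  p0 <- sampling_zero_prob(exp(1 + 0.3 * x), r = 1.2)
  expect_true(all(p >= p0))
  expect_true(all(p > 0 & p < 1))
})

test_that("discrepancy surfaces contrast binary vs normal covariates", {
  # at the (-2, -2) corner the binary design's two covariate levels give
  # nearly offsetting d values (mean d ~ 0) while the normal design averages
  # over extreme covariate values and keeps a large mean discrepancy; toward
  # (2, 2) the normal surface grows well past its small-slope level
  xb <- gen_covariate("bernoulli", 2000, seed = 5)
  xn <- gen_covariate("normal", 2000, seed = 5)
  mean_d <- function(x, b1, a1) {
    deflation_report(c(1, b1), c(1, a1), r = 1.2, x = x)$mean_d
  }
  expect_lt(abs(mean_d(xb, -2, -2)), 0.3)
  expect_gt(abs(mean_d(xn, -2, -2)), 1.5)
  expect_gt(abs(mean_d(xn, 2, 2)), abs(mean_d(xn, 0.1, 0.1)))
})
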