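test_that("AR(1) simulation reproduces known moments", {
  # phi = 0: iid N(1, 1)
  draws <- vapply(1:4000, function(i) {
    ar1_simulate(ar1_params(1, 0, 1, 2), 0, seed = i)$y[1]
  }, numeric(1))
  expect_within_3se_m <- abs(mean(draws) - 1) <= 3 / sqrt(4000)
  expect_true(expect_within_3se_m)

  # E[y_n] at (c = 1, phi = 0.5, n = 5) from the unrolled recursion
  yn <- vapply(1:4000, function(i) {
    ar1_simulate(ar1_params(1, 0.5, 1, 5), 0, seed = 10000 + i)$y[5]
  }, numeric(1))
  target <- (1 - 0.5^5) / (1 - 0.5)   # 1.9375
  expect_equal(target, 1.9375)
  sd_yn <- sqrt((1 - 0.5^10) / (1 - 0.25))
  expect_lte(abs(mean(yn) - target), 3 * sd_yn / sqrt(4000))

  # observed block is invariant to whether the future block is drawn
  a <- ar1_simulate(ar1_params(1, 0.5, 1, 20), 0, seed = 3)
  b <- ar1_simulate(ar1_params(1, 0.5, 1, 20), 5, seed = 3)
  expect_equal(a$y, b$y)
  expect_length(b$ytilde, 5)
})

test_that("summary statistics match their printed formulas", {
  y <- c(1, 2, 3)
  expect_equal(ar1_summaries(y, 0.5, "s1"), (0.5 * 3 + 3) / 3)  # 1.5
  expect_equal(ar1_summaries(y, 0.5, "s3"), 1.5 + 0.5 * 3)      # 3.0
  expect_equal(ar1_summaries(y, 0, "s1"), mean(y))
  expect_length(ar1_summaries(rnorm(10), 0.3, "s2"), 2)
  expect_length(ar1_summaries(rnorm(10), 0.3, "s1"), 1)
  expect_error(ar1_summaries(1, 0.5, "s1"), "two observations")
})

test_that("closed-form ABC posterior of the drift matches its definition and the conditioning oracle", {
  g <- ar1_abc_posterior_c(1.5, 1, 100, 0.1)
  expect_equal(g$mean, 1.5)
  expect_equal(g$variance, 0.01 + 0.01)
  expect_equal(ar1_abc_posterior_c(1.5, 1, 100, 0)$variance, 0.01)
  expect_error(ar1_abc_posterior_c(1, 1, 100, -1), "nonnegative")

  # independent oracle: direct joint-Gaussian conditioning gives the same law
  set.seed(9)
  for (phi in c(-0.4, 0, 0.7)) {
    y <- ar1_simulate(ar1_params(0.7, phi, 2, 40), 0, seed = 17)$y
    L <- abcpred:::ar1_summary_matrix(40, phi, "s1")
    for (h in c(0, 0.3)) {
      ref <- abcpred:::ar1_posterior_c_conditional(40, phi, 2, L, h,
                                                   drop(L %*% y))
      g <- ar1_abc_posterior_c(ar1_summaries(y, phi, "s1"), 2, 40, h)
      expect_equal(g$mean, ref$mean, tolerance = 1e-10)
      expect_equal(g$variance, ref$variance, tolerance = 1e-10)
    }
  }
})

test_that("predictive oracles satisfy the exactness and inflation properties", {
  y <- ar1_simulate(ar1_params(1, 0.5, 1, 100), 0, seed = 21)$y
  exact <- ar1_predictive_oracles(y, 0.5, 1, 0, "exact")
  expect_equal(exact$variance, 1 * (1 + 1 / 100))
  # ABC-F at h = 0 is the exact predictive; at h > 0 only the variance grows
  f0 <- ar1_predictive_oracles(y, 0.5, 1, 0, "abc_f")
  fh <- ar1_predictive_oracles(y, 0.5, 1, 0.4, "abc_f")
  expect_equal(f0$mean, exact$mean)
  expect_equal(f0$variance, exact$variance)
  expect_equal(fh$variance, exact$variance + 0.16)
  # s3 and s2 conditioning recover the exact predictive at h = 0
  for (v in c("s2", "s3")) {
    g <- ar1_predictive_oracles(y, 0.5, 1, 0, v)
    expect_equal(g$mean, exact$mean, tolerance = 1e-8)
    expect_equal(g$variance, exact$variance, tolerance = 1e-8)
  }
  # s1 alone is not predictive sufficient: strictly larger variance unless phi=0
  s1 <- ar1_predictive_oracles(y, 0.5, 1, 0, "s1_only")
  expect_gt(s1$variance, exact$variance + 0.05)
  y0 <- ar1_simulate(ar1_params(1, 0, 1, 100), 0, seed = 22)$y
  s1_iid <- ar1_predictive_oracles(y0, 0, 1, 0, "s1_only")
  ex_iid <- ar1_predictive_oracles(y0, 0, 1, 0, "exact")
  expect_equal(s1_iid$variance, ex_iid$variance, tolerance = 1e-8)
})

test_that("acceptance-probability bound follows the printed formulas", {
  # |phi| = 1: quadrupling n halves the upper bound
  b1 <- ar1_acceptance_bound(1, 1, 10, 0.1)
  b4 <- ar1_acceptance_bound(1, 1, 40, 0.1)
  expect_equal(b1$direction, "upper")
  expect_equal(b1$value / b4$value, 2)
  # |phi| < 1 branch, phi = 0: sqrt(2)*h/sqrt(pi)*exp(-h^2/2)
  b0 <- ar1_acceptance_bound(0, 1, 10, 0.1)
  expect_equal(b0$direction, "lower")
  expect_equal(b0$value, sqrt(2) * 0.1 / sqrt(pi) * exp(-0.005),
               tolerance = 1e-12)
  expect_equal(b0$value, 0.0793905, tolerance = 1e-6)
  expect_error(ar1_acceptance_bound(0.5, 1, 10, 0), "positive")

  # Monte-Carlo maximization over a c-grid respects the bound directions
  mc_max <- function(phi, n, h, m = 4000) {
    # z_n | c ~ N(c mu_n, s2_n): simulate and count matches to y_n = 0
    mu <- abcpred:::ar1_mean_coeff(n, phi)[n]
    best <- 0
    for (c0 in seq(-2, 2, length.out = 21)) {
      zs <- vapply(seq_len(m), function(i) {
        ar1_simulate(ar1_params(c0, phi, 1, n), 0,
                     seed = 90000 + i)$y[n]
      }, numeric(1))
      best <- max(best, mean(abs(zs - 0) <= h))
    }
    best
  }
  b <- ar1_acceptance_bound(1.2, 1, 10, 0.5)
  se_b <- sqrt(b$value * (1 - b$value) / 800)
  expect_lte(mc_max(1.2, 10, 0.5, m = 800), b$value + 3 * se_b)
  blo <- ar1_acceptance_bound(0.5, 1, 10, 0.5)
  se_lo <- sqrt(blo$value * (1 - blo$value) / 800)
  expect_gte(mc_max(0.5, 10, 0.5, m = 800), blo$value - 3 * se_lo)
})

test_that("Gaussian-kernel importance sampling reproduces the closed-form ABC posterior", {
  phi <- 0.5; s2 <- 1; n <- 100; h <- 0.1
  y <- ar1_simulate(ar1_params(1, phi, s2, n), 1, seed = 23)$y
  model <- ar1_model(phi, s2, n, 1)
  prior <- ar1_flat_prior()
  sfn <- function(yy) ar1_summaries(yy, phi, "s1")
  s_obs <- sfn(y)
  q <- prior_spec(function(m, seed) {
    set.seed(seed); matrix(rnorm(m, s_obs, 0.5), ncol = 1)
  }, function(theta) dnorm(theta[1], s_obs, 0.5, log = TRUE), p = 1)
  run <- abc_importance(model, prior, q, sfn, discrepancy_spec("linf"),
                        kernel_spec("gaussian", h), y, m = 10000, seed = 24,
                        target = prediction_target("ABC_F"))
  mom <- weighted_moments(run$theta[, 1], run$weights)
  oracle <- ar1_abc_posterior_c(s_obs, s2, n, h)
  expect_lte(abs(mom$mean - oracle$mean), 3 * mom$se_mean)
  expect_lte(abs(mom$var - oracle$variance), 3 * mom$se_var)
})

test_that("shrinking thresholds bring the ABC-P predictive toward the exact law", {
  phi <- 0.5; n <- 50
  y <- ar1_simulate(ar1_params(1, phi, 1, n), 0, seed = 26)$y
  model <- ar1_model(phi, 1, n, 1)
  prior <- ar1_flat_prior()
  sfn <- function(yy) ar1_summaries(yy, phi, "s3")  # predictive sufficient
  s_obs <- sfn(y)
  exact <- ar1_predictive_oracles(y, phi, 1, 0, "exact")
  cdf <- function(x) pnorm(x, exact$mean, sqrt(exact$variance))
  ks <- vapply(c(2, 1, 0.5, 0.25), function(h) {
    run <- abc_importance(model, prior, NULL, sfn, discrepancy_spec("linf"),
                          kernel_spec("uniform", h), y, m = 20000, seed = 27,
                          target = prediction_target("ABC_P"))
    ks_distance(run$ytilde[, 1], cdf, run$weights)
  }, numeric(1))
  # non-increasing within Monte-Carlo noise, and clearly smaller at the end
  expect_true(all(diff(ks) <= 0.05))
  expect_lt(ks[4], ks[1])
})
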