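test_that("kernel evaluation follows the uniform and Gaussian definitions", {
  expect_equal(evaluate_kernel(kernel_spec("uniform", 1), 0.5), 1)
  expect_equal(evaluate_kernel(kernel_spec("uniform", 1), 1.5), 0)
  expect_equal(evaluate_kernel(kernel_spec("uniform", 1), 1), 1)  # tie accepted
  expect_equal(evaluate_kernel(kernel_spec("gaussian", 2), 0), 1)
  expect_equal(evaluate_kernel(kernel_spec("gaussian", 2), 2), exp(-0.5))
  expect_equal(evaluate_kernel(kernel_spec("uniform", Inf), 1e12), 1)
  expect_error(evaluate_kernel(kernel_spec("uniform", 1), -0.1), "nonnegative")
  expect_error(kernel_spec("uniform", -1), "nonnegative")
})

test_that("discrepancies match hand-computed values and are proper", {
  linf <- discrepancy_spec("linf")
  expect_equal(compute_discrepancy(linf, c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(compute_discrepancy(linf, c(0, 0, 0), c(1, -4, 2)), 4)
  idw <- discrepancy_spec("weighted", weights = c(1, 1))
  expect_equal(compute_discrepancy(idw, c(1, 0), c(0, 0)), 1)
  mah <- discrepancy_spec("mahalanobis", weights = diag(2))
  expect_equal(compute_discrepancy(mah, c(1, 0), c(0, 0)), 1)
  expect_error(compute_discrepancy(linf, 1:3, 1:2), "length")
  expect_error(discrepancy_spec("mahalanobis", weights = matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")

  # symmetry and identity of indiscernibles across norm kinds
  set.seed(1)
  C <- crossprod(matrix(rnorm(9), 3))
  specs <- list(linf, discrepancy_spec("weighted", weights = runif(3, 0.5, 2)),
                discrepancy_spec("mahalanobis", weights = C))
  for (sp in specs) {
    for (k in 1:20) {
      a <- rnorm(3); b <- rnorm(3)
      expect_equal(compute_discrepancy(sp, a, b), compute_discrepancy(sp, b, a))
      expect_equal(compute_discrepancy(sp, a, a), 0)
      expect_gt(compute_discrepancy(sp, a, b), 0)
    }
  }
})

test_that("product kernel accepts iff both blocks are within their thresholds", {
  part <- list(bar = 1:2, tilde = 3:4)
  linf <- discrepancy_spec("linf")
  s <- c(1, 2, 3, 4)
  expect_equal(product_kernel_accept(s, s, part, linf, linf, 0, 0), 1)
  expect_equal(product_kernel_accept(s, c(1, 2, 9, 4), part, linf, linf, 1, 1), 0)
  expect_equal(product_kernel_accept(s, c(1.5, 2, 3.5, 4), part, linf, linf,
                                     0.5, 0.5), 1)
  expect_error(product_kernel_accept(s, s, NULL, linf, linf, 1, 1), "partition")

  # empty prediction block reduces to the single-kernel uniform rule
  part1 <- list(bar = 1:3, tilde = integer(0))
  kern <- kernel_spec("uniform", 0.8)
  set.seed(42)
  for (k in 1:100) {
    a <- rnorm(3); b <- a + rnorm(3, sd = 0.5)
    expect_equal(product_kernel_accept(a, b, part1, linf, linf, 0.8, 0),
                 evaluate_kernel(kern, compute_discrepancy(linf, a, b)))
  }
})

test_that("product-kernel acceptance region equals a scaled max-norm ball", {
  # with h_bar/a = h_tilde/b = h the region is {max(a||.||, b||.||') <= h}
  part <- list(bar = 1:2, tilde = 3:5)
  l2sq <- discrepancy_spec("weighted", weights = c(1, 1))
  linf <- discrepancy_spec("linf")
  a <- 2; b <- 0.5; h <- 0.7
  set.seed(7)
  for (k in 1:1000) {
    sy <- rnorm(5); sz <- sy + rnorm(5, sd = 1.2)
    lhs <- product_kernel_accept(sy, sz, part, l2sq, linf, h * a, h * b)
    d1 <- compute_discrepancy(l2sq, sy[1:2], sz[1:2])
    d2 <- compute_discrepancy(linf, sy[3:5], sz[3:5])
    rhs <- as.numeric(max(d1 / a, d2 / b) <= h)
    expect_equal(lhs, rhs)
  }
})

test_that("pilot weight estimation recovers known scales and flags degeneracy", {
  # model whose summaries are iid N(0, 4) per coordinate
  m <- simulator_model("iidnorm", "JOINT",
                       simulate_joint = function(theta, seed, predict = TRUE, ...) {
                         set.seed(seed)
                         list(y = rnorm(3, sd = 2), ytilde = NULL)
                       }, theta_names = "mu")
  w <- estimate_summary_weights(m, 0, function(y) y, n_pilot = 2000,
                                method = "mad", seed = 5)
  expect_s3_class(w, "abc_discrepancy")
  # MAD of N(0, 4) is 2 * 0.6745; weights 1/MAD^2 within MC error
  expect_equal(unname(w$weights), rep(1 / (2 * qnorm(0.75))^2, 3),
               tolerance = 0.15)
  Cw <- estimate_summary_weights(m, 0, function(y) y, n_pilot = 2000,
                                 method = "cov", seed = 6)
  expect_equal(unname(diag(Cw$weights)), rep(4, 3), tolerance = 0.15)
  expect_lt(max(abs(Cw$weights[upper.tri(Cw$weights)])), 0.5)

  m_bad <- simulator_model("degenerate", "JOINT",
                           simulate_joint = function(theta, seed, predict = TRUE, ...) {
                             set.seed(seed)
                             list(y = c(rnorm(2), 7), ytilde = NULL)
                           }, theta_names = "mu")
  expect_error(estimate_summary_weights(m_bad, 0, function(y) y, n_pilot = 50,
                                        method = "cov", seed = 1),
               "coordinate.*3")
})

test_that("threshold calibration hits the target rate and is monotone", {
  expect_equal(calibrate_threshold(1:100, 0.02), 2)
  expect_equal(calibrate_threshold(1:100, 1.0), 100)
  expect_equal(calibrate_threshold(rep(5, 40), 0.37), 5)
  expect_error(calibrate_threshold(numeric(0), 0.1), "no discrepancy")
  set.seed(3)
  d <- rexp(500)
  rates <- seq(0.05, 1, by = 0.05)
  hs <- vapply(rates, function(r) calibrate_threshold(d, r), numeric(1))
  expect_true(all(diff(hs) >= 0))
  for (r in c(0.05, 0.5)) {
    h <- calibrate_threshold(d, r)
    expect_lte(abs(mean(d <= h) - r), 1 / length(d) + 1e-12)
  }
})

test_that("weight normalization and ESS behave as defined", {
  expect_equal(normalize_and_ess(c(1, 1, 1, 1))$ess, 4)
  expect_equal(normalize_and_ess(c(1, 0, 0, 0))$ess, 1)
  r <- normalize_and_ess(c(2, 1, 1))
  expect_equal(r$weights, c(0.5, 0.25, 0.25))
  expect_equal(r$ess, 8 / 3)
  expect_error(normalize_and_ess(c(0, 0)), "zero")
  expect_warning(normalize_and_ess(c(1, rep(1e-12, 200))), "effective sample size")
})
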