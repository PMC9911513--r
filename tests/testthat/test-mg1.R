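test_that("queue recursion matches the hand-unrolled example", {
  tr <- mg1_simulate(mg1_params(0.5, 1.5, 1), n = 2, u = c(1, 1), w = c(2, 5))
  expect_equal(tr$v, c(2, 7))
  expect_equal(tr$y, c(3, 5))
  expect_equal(tr$x, c(3, 8))
  expect_equal(tr$omega, c(1, 1))
})

test_that("zero service times give zero waiting and departure = arrival", {
  tr <- mg1_simulate(mg1_params(0, 0, 0.3), n = 50, seed = 1)
  expect_true(all(tr$omega == 0))
  expect_equal(tr$x, tr$v)
  expect_equal(tr$y, diff(c(0, tr$x)))
})

test_that("service times have the declared uniform mean and waiting times respect the floor", {
  pars <- mg1_params(4, 7, 0.15)
  us <- unlist(lapply(1:300, function(i) mg1_simulate(pars, 30, seed = i)$u))
  expect_lte(abs(mean(us) - 5.5), 3 * sqrt(3^2 / 12 / length(us)))
  for (i in 1:50) {
    tr <- mg1_simulate(pars, 60, seed = 1000 + i)
    expect_true(all(tr$omega >= 4 - 1e-9))   # omega_i >= u_i >= theta1
    expect_true(all(tr$omega >= tr$u - 1e-9))
    expect_true(all(diff(tr$v) >= 0))
    expect_equal(tr$x, cumsum(tr$y))
  }
})

test_that("conditional continuation splits the recursion exactly", {
  pars <- mg1_params(2, 5, 0.2)
  set.seed(3)
  u <- runif(30, 2, 5); w <- rexp(30, 0.2)
  full <- mg1_simulate(pars, n = 30, u = u, w = w)
  head20 <- mg1_simulate(pars, n = 20, u = u[1:20], w = w[1:20])
  cont <- mg1_conditional_predict(pars, x_n = head20$x[20], v_n = head20$v[20],
                                  ntilde = 10, u = u[21:30], w = w[21:30])
  expect_equal(cont$omega, full$omega[21:30])
  expect_equal(cont$x, full$x[21:30])
  expect_error(mg1_conditional_predict(pars, x_n = 1, v_n = 2, ntilde = 1,
                                       seed = 1), "inconsistent")
})

test_that("empty-queue restart equals a fresh simulation in law", {
  pars <- mg1_params(1, 2, 0.5)
  fresh <- vapply(1:2000, function(i) {
    mg1_simulate(pars, n = 1, seed = i)$omega[1]
  }, numeric(1))
  restart <- vapply(1:2000, function(i) {
    mg1_conditional_predict(pars, 0, 0, 1, seed = 5000 + i)$omega[1]
  }, numeric(1))
  expect_gt(ks.test(fresh, restart)$p.value, 0.01)
})

test_that("summary statistics follow the stated conventions", {
  y <- c(5, 1, 1)
  s0 <- mg1_summaries(y, "s0")
  expect_length(s0, 5)
  expect_equal(unname(s0[c("min", "max")]), c(1, 5))
  expect_equal(unname(s0[2]), 1)  # median via type-7
  # index statistics against a fixed reference threshold
  s1 <- mg1_summaries(y, "s1", y_obs_ref = rep(2, 3))  # all thresholds = 2
  expect_equal(unname(s1[6:8]), c(1, 1, 1))            # only y_1 >= 2
  s1b <- mg1_summaries(c(1, 5, 1), "s1", y_obs_ref = rep(2, 3))
  expect_equal(unname(s1b[6:8]), c(2, 2, 2))
  # all below the threshold: the max-empty convention gives 1
  s1c <- mg1_summaries(c(1, 1, 1), "s1", y_obs_ref = rep(9, 3))
  expect_equal(unname(s1c[6:8]), c(1, 1, 1))
  # bounds on self-summaries
  yy <- mg1_simulate(mg1_params(4, 7, 0.15), 100, seed = 9)$y
  idx <- mg1_summaries(yy, "s1", y_obs_ref = yy)[6:8]
  expect_true(all(idx >= 1 & idx <= 100))
  expect_error(mg1_summaries(numeric(0), "s0"), "empty")
})

test_that("the prior enforces its box and the data-dependent truncation", {
  y_obs <- mg1_simulate(mg1_params(4, 7, 0.15), 100, seed = 11)$y
  pr <- mg1_prior(y_obs)
  th <- pr$sample(5000, seed = 12)
  expect_true(all(th[, 1] <= min(y_obs)))
  expect_true(all(th[, 2] >= th[, 1]))
  expect_true(all(th[, 2] - th[, 1] <= 10))
  expect_gt(ks.test(th[, 3], "punif", 0, 1 / 3)$p.value, 0.01)
  expect_equal(pr$log_density(c(min(y_obs) + 0.1, 12, 0.2)), -Inf)
  expect_equal(pr$log_density(c(1, 2, 0.2)), 0)
  # inactive truncation: theta1 uniform on [0, 10]
  pr2 <- mg1_prior(rep(50, 10))
  th2 <- pr2$sample(5000, seed = 13)
  expect_gt(ks.test(th2[, 1], "punif", 0, 10)$p.value, 0.01)
})

test_that("the growing-queue regime has linearly growing waiting times", {
  slopes <- vapply(1:100, function(i) {
    tr <- mg1_simulate(mg1_params(8, 16, 0.15), 100, seed = 2000 + i)
    unname(coef(lm(tr$omega ~ seq_along(tr$omega)))[2])
  }, numeric(1))
  tstat <- mean(slopes) / (sd(slopes) / sqrt(length(slopes)))
  expect_gt(tstat, 5)
  expect_gt(mean(slopes), 0)
})
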