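test_that("the empty state is absorbing", {
  tr <- lv_gillespie(lv_params(1, 0.005, 0.6, c(0, 0)), seq(0, 5, 1), seed = 1)
  expect_true(all(tr$states == 0))
  expect_equal(tr$n_events, 0)
})

test_that("pure prey birth reproduces the exponential-growth mean", {
  # theta2 = theta3 = 0: prey is a pure birth process, mean y0 * exp(theta1 t)
  n_rep <- 3000
  finals <- vapply(1:n_rep, function(i) {
    lv_gillespie(lv_params(0.5, 0, 0, c(100, 0)), c(0, 1), seed = i)$states[1, 2]
  }, numeric(1))
  m_target <- 100 * exp(0.5)
  v_target <- 100 * exp(1) * (1 - exp(-0.5))  # birth-process variance
  expect_lte(abs(mean(finals) - m_target), 3 * sqrt(v_target / n_rep))
})

test_that("event types follow the propensity ratios from random states", {
  set.seed(4)
  for (k in 1:5) {
    w <- c(sample(20:200, 1), sample(10:100, 1))
    th <- c(runif(1, 0.5, 2), runif(1, 0.001, 0.01), runif(1, 0.2, 1))
    gam <- th[1] * w[1] + th[2] * w[1] * w[2] + th[3] * w[2]
    probs <- c(th[1] * w[1], th[2] * w[1] * w[2], th[3] * w[2]) / gam
    n_ev <- 4000
    types <- vapply(1:n_ev, function(i) {
      tr <- lv_gillespie(lv_params(th[1], th[2], th[3], w), c(0, 1e6),
                         seed = 10000 * k + i, event_cap = 1,
                         return_path = TRUE)
      d <- c(tr$path$y1[2] - tr$path$y1[1], tr$path$y2[2] - tr$path$y2[1])
      if (d[1] == 1) 1L else if (d[1] == -1) 2L else 3L
    }, integer(1))
    emp <- tabulate(types, 3) / n_ev
    expect_within_3se(emp, probs, n_ev, info = sprintf("state %d/%d", w[1], w[2]))
  }
})

test_that("every event changes the state by one reaction vector", {
  tr <- lv_gillespie(lv_params(1, 0.005, 0.6, c(50, 30)), c(0, 3), seed = 6,
                     return_path = TRUE)
  d <- cbind(diff(tr$path$y1), diff(tr$path$y2))
  legal <- (d[, 1] == 1 & d[, 2] == 0) |
    (d[, 1] == -1 & d[, 2] == 1) |
    (d[, 1] == 0 & d[, 2] == -1)
  expect_true(all(legal))
  expect_true(all(tr$states >= 0))
})

test_that("capped trajectories are flagged and carried forward", {
  tr <- lv_gillespie(lv_params(5, 1e-8, 1e-8, c(100, 0)), c(0, 10), seed = 7,
                     pop_cap = 1e4)
  expect_true(tr$capped)
  expect_equal(tr$states[1, 2], tr$states[1, ncol(tr$states)])
})

test_that("summary dimensions and conventions match the scenarios", {
  s1 <- lv_scheme("predict_case1")
  s2 <- lv_scheme("predict_case2")
  s3 <- lv_scheme("missing_data")
  expect_length(s1$obs_idx, 81)
  expect_length(s1$pred_idx, 70)
  expect_length(s3$w1_idx, 51)
  expect_length(s3$pred_idx, 69)

  fx1 <- generate_fixture("lv", seed = 8, scenario = "predict_case1")
  sm1 <- lv_summaries(fx1$y_obs, s1)
  expect_length(sm1$value, 11)
  expect_length(sm1$partition$bar, 9)
  expect_length(sm1$partition$tilde, 2)

  fx2 <- generate_fixture("lv", seed = 8, scenario = "predict_case2")
  sm2 <- lv_summaries(fx2$y_obs, s2)
  expect_length(sm2$value, 10)
  expect_length(sm2$partition$bar, 4)

  fx3 <- generate_fixture("lv", seed = 8, scenario = "missing_data")
  sm3 <- lv_summaries(fx3$y_obs, s3)
  expect_length(sm3$value, 12)
  expect_length(sm3$partition$bar, 8)

  # alternating series: autocorrelations from the direct closed form under
  # the biased (1/n) normalization: -(n-1)/n at lag 1, (n-2)/n at lag 2
  n <- 40
  alt <- rep(c(2, 6), n / 2)
  expect_equal(abcpred:::acf_lag(alt, 1), -(n - 1) / n, tolerance = 1e-12)
  expect_equal(abcpred:::acf_lag(alt, 2), (n - 2) / n, tolerance = 1e-12)
  expect_error(abcpred:::acf_lag(rep(3, 10), 1), "constant")

  # identical populations: cross-correlation 1
  y_ident <- c(fx2$y_obs, fx2$y_obs)  # case-1 layout with prey == predator
  expect_equal(unname(lv_summaries(y_ident, s1)$value["cross"]), 1)
})

test_that("the log-uniform prior has the stated box and density", {
  pr <- lv_prior()
  th <- pr$sample(5000, seed = 9)
  expect_true(all(log(th) >= -6 & log(th) <= 2))
  expect_equal(pr$log_density(c(1, 0.005, 0.6)), -3 * log(8))
  expect_equal(pr$log_density(c(1, exp(-7), 0.6)), -Inf)
  expect_true(is.finite(pr$log_density(c(1, 0.005, 0.6))))
})

test_that("ideal predictive baselines accept in nested fashion", {
  fx <- generate_fixture("lv", seed = 10, scenario = "missing_data")
  scheme <- lv_scheme("missing_data")
  all_in <- lv_ideal_predictive(lv_params(1, 0.005, 0.6), fx$y_obs, scheme,
                                tol = Inf, m = 100, seed = 11)
  expect_equal(all_in$acceptance_rate, 1)
  rates <- vapply(c(Inf, 50, 20), function(tol) {
    r <- tryCatch(lv_ideal_predictive(lv_params(1, 0.005, 0.6), fx$y_obs,
                                      scheme, tol = tol, m = 200, seed = 12),
                  error = function(e) list(acceptance_rate = 0))
    r$acceptance_rate
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))  # same simulation batch, nested regions
})
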