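test_that("accept-all limit returns the prior as theta marginal", {
  ts <- toy_setup()
  run <- abc_rejection(ts$model, ts$prior, ts$summary_fn, ts$disc,
                       kernel_spec("uniform", Inf), y_obs = 1, m = 4000,
                       seed = 1, target = prediction_target("ABC_P"))
  expect_equal(run$acceptance_rate, 1)
  expect_within_3se(mean(run$theta[, 1]), 0.5, 4000)
})

test_that("rejection, importance and MCMC all match the enumerated joint law", {
  ts <- toy_setup()
  truth <- bernoulli_toy_enumerate()
  m <- 20000
  rej <- abc_rejection(ts$model, ts$prior, ts$summary_fn, ts$disc, ts$kernel,
                       y_obs = 1, m = m, seed = 2,
                       target = prediction_target("ABC_P"))
  expect_within_3se(toy_joint(rej), truth, length(rej), "rejection")

  imp <- abc_importance(ts$model, ts$prior, toy_proposal(0.3), ts$summary_fn,
                        ts$disc, ts$kernel, y_obs = 1, m = m, seed = 3,
                        target = prediction_target("ABC_P"))
  expect_within_3se(toy_joint(imp), truth, imp$ess, "importance q != prior")

  flip <- list(sample = function(theta, seed) {
    set.seed(seed); matrix(1 - round(theta[1]), 1)
  }, log_density = function(to, from) 0)
  chain <- abc_mcmc(ts$model, ts$prior, ts$summary_fn, ts$disc, ts$kernel,
                    mcmc_config(m, burn_in = 1000, adapt = FALSE),
                    y_obs = 1, seed = 4,
                    target = prediction_target("ABC_P"), proposal = flip)
  # correlated draws: use a conservative effective size
  expect_within_3se(toy_joint(chain), truth, length(chain) / 4, "mcmc")
})

test_that("importance weights reduce to kernel values when q equals the prior", {
  ts <- toy_setup()
  kern <- kernel_spec("uniform", 0)
  rej <- abc_rejection(ts$model, ts$prior, ts$summary_fn, ts$disc, kern,
                       y_obs = 1, m = 3000, seed = 5,
                       target = prediction_target("ABC_P"))
  imp <- abc_importance(ts$model, ts$prior, NULL, ts$summary_fn, ts$disc, kern,
                        y_obs = 1, m = 3000, seed = 5,
                        target = prediction_target("ABC_P"))
  # identical seed stream + q = prior: same accepted records, equal weights
  expect_equal(imp$theta, rej$theta)
  expect_true(all(abs(imp$weights - 1 / length(imp)) < 1e-12))
})

test_that("the theta marginal of an ABC-P run equals the standard ABC run", {
  model <- ar1_model(0.5, 1, 50, 1)
  prior <- ar1_flat_prior()
  sfn <- function(y) ar1_summaries(y, 0.5, "s1")
  disc <- discrepancy_spec("linf")
  kern <- kernel_spec("uniform", 0.2)
  y <- ar1_simulate(ar1_params(1, 0.5, 1, 50), 1, seed = 30)$y
  rP <- abc_rejection(model, prior, sfn, disc, kern, y, m = 3000, seed = 31,
                      target = prediction_target("ABC_P"))
  rS <- abc_rejection(model, prior, sfn, disc, kern, y, m = 3000, seed = 31,
                      target = prediction_target("POSTERIOR"))
  expect_identical(rP$theta, rS$theta)
  expect_null(rS$ytilde)
  expect_false(is.null(rP$ytilde))
})

test_that("h = Inf makes the ABC-P predictive the prior predictive", {
  model <- ar1_model(0.5, 1, 30, 1)
  prior <- uniform_prior(-3, 3, names = "c")
  sfn <- function(y) ar1_summaries(y, 0.5, "s1")
  y <- ar1_simulate(ar1_params(1, 0.5, 1, 30), 1, seed = 40)$y
  run <- abc_rejection(model, prior, sfn, discrepancy_spec("linf"),
                       kernel_spec("uniform", Inf), y, m = 4000, seed = 41,
                       target = prediction_target("ABC_P"))
  # direct prior-predictive simulation
  set.seed(42)
  cs <- runif(4000, -3, 3)
  direct <- vapply(seq_along(cs), function(i) {
    sim <- ar1_simulate(ar1_params(cs[i], 0.5, 1, 30), 1, seed = 5000 + i)
    sim$ytilde[1]
  }, numeric(1))
  expect_gt(ks.test(run$ytilde[, 1], direct)$p.value, 0.01)
})

test_that("ABC-F predictions follow the conditional law given a single theta", {
  model <- ar1_model(0.6, 1, 20, 1)
  y <- ar1_simulate(ar1_params(1, 0.6, 1, 20), 1, seed = 50)$y
  one <- weighted_samples(theta = matrix(2), weights = 1, mode = "POSTERIOR")
  pred <- abc_f_predict(one, model, y, seed = 51)
  expect_equal(dim(pred$ytilde), c(1, 1))
  # many draws at the same theta: law is N(c + phi*y_n, sigma2)
  many <- weighted_samples(theta = matrix(rep(2, 4000)), mode = "POSTERIOR")
  pred <- abc_f_predict(many, model, y, seed = 52)
  expect_gt(ks.test(pred$ytilde[, 1], "pnorm",
                    2 + 0.6 * y[20], 1)$p.value, 0.01)
})

test_that("prediction modes are validated against model capabilities", {
  model <- ar1_model(0.5, 1, 20, 1)
  no_pred <- simulator_model("bare", "JOINT",
                             simulate_joint = model$simulate_joint)
  expect_error(abc_f_predict(weighted_samples(matrix(1)), no_pred,
                             rnorm(20), seed = 1), "COND_PRED")
  expect_error(check_target <- abcpred:::check_target(no_pred,
                                                      prediction_target("ABC_L")),
               "JOINT_LATENT")
})

test_that("deferred prediction matches joint simulation distributionally", {
  model <- mg1_model(n = 40, ntilde = 3)
  prior <- mg1_prior(rep(10, 40))
  fxp <- mg1_params(4, 7, 0.15)
  y <- mg1_simulate(fxp, 40, seed = 60)$y
  sfn <- function(z) mg1_summaries(z, "s0")
  disc <- estimate_summary_weights(model, c(4, 7, 0.15), sfn, n_pilot = 200,
                                   method = "cov", seed = 61)
  kern <- kernel_spec("uniform", 60)
  joint <- abc_rejection(model, prior, sfn, disc, kern, y, m = 4000, seed = 62,
                         target = prediction_target("ABC_P"))
  defer <- abc_rejection(model, prior, sfn, disc, kern, y, m = 4000, seed = 62,
                         target = prediction_target("ABC_P", deferred = TRUE))
  defer <- deferred_prediction(defer, model, seed = 63)
  expect_identical(joint$theta, defer$theta)
  expect_gt(ks.test(joint$ytilde[, 1], defer$ytilde[, 1])$p.value, 0.01)

  # empty index set and zero-weight exclusion
  empty <- deferred_prediction(defer, model, which = integer(0), seed = 64)
  expect_equal(length(empty), 0)
  expect_error(deferred_prediction(defer, model, which = 10 * length(defer),
                                   seed = 65), "outside")
})

test_that("MCMC satisfies detailed balance on the discrete toy model", {
  ts <- toy_setup()
  flip <- list(sample = function(theta, seed) {
    set.seed(seed); matrix(1 - round(theta[1]), 1)
  }, log_density = function(to, from) 0)
  chain <- abc_mcmc(ts$model, ts$prior, ts$summary_fn, ts$disc,
                    kernel_spec("uniform", 0),
                    mcmc_config(30000, burn_in = 1000, adapt = FALSE),
                    y_obs = 1, seed = 70,
                    target = prediction_target("POSTERIOR"), proposal = flip)
  th <- round(chain$theta[, 1])
  n01 <- sum(th[-length(th)] == 0 & th[-1] == 1)
  n10 <- sum(th[-length(th)] == 1 & th[-1] == 0)
  # flows across states should balance within 3 SEs of the transition counts
  expect_lte(abs(n01 - n10), 3 * sqrt(n01 + n10))
})

test_that("MCMC threshold tuning approaches the target acceptance rate", {
  model <- ar1_model(0.5, 1, 50, 1)
  prior <- ar1_flat_prior()
  sfn <- function(y) ar1_summaries(y, 0.5, "s1")
  disc <- discrepancy_spec("linf")
  y <- ar1_simulate(ar1_params(1, 0.5, 1, 50), 1, seed = 80)$y
  cfg <- mcmc_config(10000, burn_in = 2000, proposal_scale = 0.5,
                     target_accept = 0.1)
  tuned <- tune_mcmc_threshold(model, prior, sfn, disc,
                               kernel_spec("uniform", 1), cfg, y, seed = 81,
                               rate = 0.1, n_pilot = 2000)
  expect_true(is.finite(tuned$kernel$h))
  expect_lte(abs(tuned$rate - 0.1) / 0.1, 0.5)
})
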