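# shared small objects for the unit tests

toy_setup <- function() {
  list(model = bernoulli_toy_model(),
       prior = bernoulli_toy_prior(),
       summary_fn = function(y) y,
       disc = discrepancy_spec("linf"),
       kernel = kernel_spec("uniform", 0))
}

# proposal on {0,1} with P(theta = 1) = q1
toy_proposal <- function(q1) {
  prior_spec(
    sample = function(n, seed) {
      set.seed(seed)
      matrix(as.numeric(stats::runif(n) < q1), ncol = 1)
    },
    log_density = function(theta) {
      log(if (round(theta[1]) == 1) q1 else 1 - q1)
    },
    p = 1L)
}

# empirical joint law of (theta, ytilde) from a sample set (weighted)
toy_joint <- function(run) {
  out <- matrix(0, 2, 2)
  for (th in 0:1) for (yt in 0:1) {
    out[th + 1, yt + 1] <- sum(run$weights[run$theta[, 1] == th &
                                             run$ytilde[, 1] == yt])
  }
  out
}

expect_within_3se <- function(emp, truth, n_eff, info = NULL) {
  se <- sqrt(pmax(truth * (1 - truth), 1e-12) / n_eff)
  expect_true(all(abs(emp - truth) <= 3 * se + 1e-12), info = info)
}
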