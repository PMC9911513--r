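# abcpred

Posterior **predictive** inference for simulator models with intractable
likelihoods, via approximate Bayesian computation (ABC).

## The problem

For a model where the likelihood π(y | θ) can only be *simulated*, standard
ABC approximates the parameter posterior by accepting parameter draws whose
simulated summaries s(z) fall within a threshold h of the observed ones
s(y).  This package targets the posterior predictive distribution
π(ỹ | y) = ∫ π(ỹ | y, θ) π(θ | y) dθ of future or missing data ỹ, with
three complementary approximations distinguished by which conditional laws
of the simulator are available:

| method | needs sampling from | target |
|--------|--------------------|--------|
| ABC-F  | π(ỹ \| y, θ) and π(y \| θ) | ∫ π(ỹ \| θ, y) π̂ₕ(θ \| s_y) dθ |
| ABC-P  | π(ỹ, y \| θ) jointly | π̂ₕ⁽ᴾ⁾(ỹ \| s_y) ∝ ∬ Kₕ(Δ(s_y, s_z)) π(ỹ, s_z \| θ) π(θ) ds_z dθ |
| ABC-L  | π(ỹ \| y, v, θ) and π(y, v \| θ) | ∬ π(ỹ \| y, v, θ) π̂ₕ(v, θ \| s_y) dv dθ |

ABC-P needs a summary that is *predictive sufficient*
(π(ỹ | y) = π(ỹ | s_y)), not merely sufficient for θ — the practical
recipe is a two-block product kernel
𝟙{‖s̄_y − s̄_z‖ ≤ h̄} · 𝟙{‖s̃_y − s̃_z‖′ ≤ h̃} with a parameter-informative
block s̄ and a prediction-informative block s̃.  Rejection, self-normalized
importance sampling and ABC-MCMC samplers for the augmented targets are
provided, including deferred prediction (simulate ỹ only for retained
draws; exact because the acceptance probability never depends on ỹ).

Audience: statisticians and computational biologists doing likelihood-free
inference who need forecasts or missing-data reconstruction, not just
parameter estimates.

## Bundled models

* **AR(1) Gaussian Markov chain** with closed-form ABC posterior
  N(ȳ_φ, σ²/n + h²) and predictive oracles for every summary variant —
  the analytic test bed for sufficiency effects.
* **Gaussian linear state-space model** with exact sufficiency identities
  for (vₙ, c) via joint-normal conditioning.
* **M/G/1 queue** (uniform service, Poisson arrivals; only interdeparture
  times observed) — waiting-time prediction with ABC-P and ABC-L.
* **Stochastic Lotka–Volterra** predator–prey Markov jump process,
  simulated exactly with a compiled Gillespie algorithm — forecasting and
  missing-data scenarios, including prey-only observation.

## Worked example

Approximate the ABC posterior of the AR(1) drift c by importance sampling
with a Gaussian kernel, and compare with the closed form:

```r
library(abcpred)

y <- ar1_simulate(ar1_params(c = 1, phi = 0.5, sigma2 = 1, n = 100),
                  n_future = 1, seed = 11)$y
model <- ar1_model(phi = 0.5, sigma2 = 1, n = 100, n_future = 1)
sfn   <- function(z) ar1_summaries(z, 0.5, "s1")
s_obs <- sfn(y)                       # 0.8764863

q <- prior_spec(function(m, seed) { set.seed(seed); matrix(rnorm(m, s_obs, 0.5)) },
                function(theta) dnorm(theta[1], s_obs, 0.5, log = TRUE), p = 1)
run <- abc_importance(model, ar1_flat_prior(), q, sfn,
                      discrepancy_spec("linf"), kernel_spec("gaussian", 0.1),
                      y_obs = y, m = 20000, seed = 12,
                      target = prediction_target("ABC_F"))
weighted_moments(run$theta[, 1], run$weights)[c("mean", "var")]
#> $mean
#> [1] 0.8786357        # oracle mean  0.8764863  (Eq.: N(ȳ_φ, σ²/n + h²))
#> $var
#> [1] 0.01978242       # oracle variance 0.02

pred <- abc_f_predict(run, model, y, seed = 13)
weighted_moments(pred$ytilde[, 1], pred$weights)[c("mean", "var")]
#> $mean
#> [1] 1.871741         # oracle mean  1.863697  (ȳ_φ + φ yₙ)
#> $var
#> [1] 1.029915         # oracle variance 1.02   (σ²(1 + 1/n) + h²)
```

The Monte-Carlo moments land within sampling error of the analytic ABC
posterior N(0.876, 0.02) and ABC-F predictive N(1.864, 1.02): the sampler
and the closed form agree.

Higher-level experiment driver (fixture generation, pilot weighting,
threshold calibration to a target acceptance rate, MCMC, predictive
summaries, CSV/JSON serialization):

```r
res <- run_experiment(list(model = "lv", scenario = "predict_case1",
                           mode = "P", summary = "s1",
                           iterations = 3e4, burn_in = 3e3,
                           accept_rate = 0.02, seed = 1),
                      out_dir = "lv_run")
attr(res$summary, "mae")   # mean absolute error of the median prediction
```

A thin command-line wrapper over the same driver lives at
`inst/scripts/abc-run.R`
(`Rscript inst/scripts/abc-run.R --config cfg.json --seed 1 --out dir/`).

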