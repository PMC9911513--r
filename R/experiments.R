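#' Weighted predictive summary
#'
#' Per-coordinate weighted median and central credible-interval bounds of the
#' predictive draws in a sample set, with optional error metrics against a
#' held-out truth.
#'
#' @param samples an [weighted_samples()] with predictive draws `ytilde`, or
#'   a plain matrix of draws.
#' @param levels central credible-interval levels.
#' @param truth optional held-out true values (one per coordinate).
#' @param weights weights when `samples` is a matrix.
#' @return a data frame with one row per predicted coordinate: `median`,
#'   `lo`/`hi` bounds per level, and `truth`/`abs_err` when supplied; the
#'   overall mean absolute error of the median prediction is attached as
#'   attribute `"mae"`.
#' @export
summarize_predictive <- function(samples, levels = c(0.75, 0.90),
                                 truth = NULL, weights = NULL) {
  if (inherits(samples, "abc_samples")) {
    if (is.null(samples$ytilde)) stop("sample set has no predictive draws")
    yt <- samples$ytilde
    w <- samples$weights
  } else {
    yt <- as.matrix(samples)
    w <- weights
  }
  if (nrow(yt) == 0L) stop("empty predictive sample")
  probs <- sort(unique(c(0.5, (1 - levels) / 2, 1 - (1 - levels) / 2)))
  qs <- t(apply(yt, 2, weighted_quantile, w = w, probs = probs))
  out <- data.frame(coord = seq_len(ncol(yt)),
                    median = qs[, match(0.5, probs)])
  for (lv in levels) {
    out[[sprintf("lo%g", 100 * lv)]] <- qs[, match((1 - lv) / 2, probs)]
    out[[sprintf("hi%g", 100 * lv)]] <- qs[, match(1 - (1 - lv) / 2, probs)]
  }
  if (!is.null(truth)) {
    stopifnot(length(truth) == ncol(yt))
    out$truth <- truth
    out$abs_err <- abs(out$median - truth)
    attr(out, "mae") <- mean(out$abs_err)
  }
  out
}

#' Mean absolute error of a median prediction
#'
#' Mean of coordinatewise absolute differences; for the predator-prey
#' experiments the mean runs over both populations and all predicted grid
#' times, against the held-out realized trajectory.
#'
#' @param prediction,truth numeric vectors of equal length.
#' @export
mae <- function(prediction, truth) {
  if (length(prediction) != length(truth)) {
    stop("prediction and truth have different lengths")
  }
  mean(abs(prediction - truth))
}

#' Discrete Bernoulli toy model with a brute-force enumerable ABC-P target
#'
#' Two-point parameter \eqn{\theta \in \{0, 1\}} with uniform prior;
#' pseudo-data \eqn{z \mid \theta \sim \mathrm{Bern}(0.2 + 0.6\theta)} and an
#' independent future draw \eqn{\tilde y} from the same law.  The summary is
#' `z` itself.  With a uniform kernel at \eqn{h = 0} and observed
#' \eqn{s_y = 1}, the ABC-P joint law of \eqn{(\theta, \tilde y)} can be
#' enumerated exactly over the 8 outcomes of \eqn{(\theta, z, \tilde y)} —
#' the package's sampler-independent oracle for rejection, importance and
#' MCMC sampling.
#'
#' @return an [simulator_model()]; the parameter is carried as a real in
#'   `{0, 1}`.
#' @export
bernoulli_toy_model <- function() {
  simulate_joint <- function(theta, seed, predict = TRUE, ...) {
    set.seed(seed)
    p <- 0.2 + 0.6 * round(theta[1])
    draws <- stats::runif(2) < p
    list(y = as.numeric(draws[1]),
         ytilde = if (predict) as.numeric(draws[2]) else NULL,
         v = as.numeric(draws[1]))
  }
  cond_pred <- function(theta, y, seed) {
    set.seed(seed)
    as.numeric(stats::runif(1) < 0.2 + 0.6 * round(theta[1]))
  }
  simulator_model("bernoulli_toy", capabilities = c("JOINT", "COND_PRED"),
                  simulate_joint = simulate_joint, cond_pred = cond_pred,
                  theta_names = "theta", log_scale = FALSE)
}

#' @rdname bernoulli_toy_model
#' @param s_y observed summary (0 or 1).
#' @param h uniform-kernel threshold.
#' @param q1 proposal probability of \eqn{\theta = 1} (enumeration is
#'   proposal-free; exposed for the importance-sampling oracle checks).
#' @return `bernoulli_toy_enumerate`: 2x2 matrix of exact ABC-P joint
#'   probabilities of \eqn{(\theta, \tilde y)} (rows: theta 0/1, cols:
#'   ytilde 0/1).
#' @export
bernoulli_toy_enumerate <- function(s_y = 1, h = 0, q1 = 0.5) {
  joint <- matrix(0, 2, 2, dimnames = list(theta = 0:1, ytilde = 0:1))
  for (th in 0:1) for (z in 0:1) for (yt in 0:1) {
    p <- 0.2 + 0.6 * th
    pz <- if (z == 1) p else 1 - p
    pyt <- if (yt == 1) p else 1 - p
    k <- as.numeric(abs(z - s_y) <= h)
    joint[th + 1, yt + 1] <- joint[th + 1, yt + 1] + 0.5 * pz * pyt * k
  }
  joint / sum(joint)
}

#' @rdname bernoulli_toy_model
#' @export
bernoulli_toy_prior <- function() {
  prior_spec(sample = function(n, seed) {
    set.seed(seed)
    matrix(as.numeric(stats::runif(n) < 0.5), ncol = 1,
           dimnames = list(NULL, "theta"))
  },
  log_density = function(theta) {
    if (round(theta[1]) %in% c(0, 1)) log(0.5) else -Inf
  }, p = 1L, names = "theta")
}

#' Generate a simulated experiment fixture
#'
#' Draws one data realization at the true parameter and splits it into an
#' observed part and a held-out truth for error metrics (the observed /
#' unobserved split of the experiment figures).
#'
#' @param model one of "ar1", "mg1", "lv".
#' @param seed integer seed.
#' @param scenario for "mg1": "varying" (\eqn{\theta_{true} = (4, 7, 0.15)})
#'   or "growing" (\eqn{\theta_{true} = (8, 16, 0.15)}); for "lv": an
#'   [lv_scheme()] scenario name.
#' @param out_dir optional directory; when given, the observed data and
#'   held-out truth are written as CSV and the metadata as JSON.
#' @param ... model settings (`n`, `ntilde`, `phi`, `sigma2`, ...).
#' @return list with `y_obs`, `truth` (held-out future/missing block),
#'   `theta_true` and model metadata.
#' @export
generate_fixture <- function(model = c("ar1", "mg1", "lv"), seed,
                             scenario = NULL, out_dir = NULL, ...) {
  model <- match.arg(model)
  args <- list(...)
  fx <- if (model == "ar1") {
    n <- args$n %||% 100L
    phi <- args$phi %||% 0.5
    sigma2 <- args$sigma2 %||% 1
    c_true <- args$c %||% 1
    n_future <- args$n_future %||% 1L
    sim <- ar1_simulate(ar1_params(c_true, phi, sigma2, n), n_future, seed)
    list(model = "ar1", y_obs = sim$y, truth = sim$ytilde,
         theta_true = c(c = c_true),
         settings = list(phi = phi, sigma2 = sigma2, n = n,
                         n_future = n_future))
  } else if (model == "mg1") {
    scenario <- scenario %||% "varying"
    theta_true <- if (scenario == "growing") c(8, 16, 0.15) else c(4, 7, 0.15)
    n <- args$n %||% 100L
    ntilde <- args$ntilde %||% 10L
    sim <- mg1_simulate(mg1_params(theta_true[1], theta_true[2],
                                   theta_true[3]),
                        n = n, ntilde = ntilde, seed = seed)
    list(model = "mg1", scenario = scenario,
         y_obs = sim$y[seq_len(n)],
         truth = sim$omega[n + seq_len(ntilde)],
         omega_obs = sim$omega[seq_len(n)],
         state = c(x_n = sim$x[n], v_n = sim$v[n]),
         theta_true = theta_true, settings = list(n = n, ntilde = ntilde))
  } else {
    scenario <- scenario %||% "predict_case1"
    scheme <- lv_scheme(scenario)
    theta_true <- c(1, 0.005, 0.6)
    pars <- lv_params(theta_true[1], theta_true[2], theta_true[3])
    tr <- lv_gillespie(pars, scheme$full, seed)
    pack <- function(idx) c(tr$states[1, idx], tr$states[2, idx])
    y_obs <- if (scenario == "predict_case2") {
      tr$states[1, scheme$obs_idx]
    } else if (scenario == "missing_data") {
      k <- length(scheme$w1_idx)
      c(tr$states[1, scheme$w1_idx], tr$states[2, scheme$w1_idx],
        tr$states[1, scheme$w2_idx], tr$states[2, scheme$w2_idx])
    } else {
      pack(scheme$obs_idx)
    }
    list(model = "lv", scenario = scenario, y_obs = y_obs,
         truth = pack(scheme$pred_idx),
         full_states = tr$states,
         theta_true = theta_true, settings = list(scheme = scheme))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(y_obs = fx$y_obs),
                     file.path(out_dir, "observed.csv"), row.names = FALSE)
    utils::write.csv(data.frame(truth = fx$truth),
                     file.path(out_dir, "truth.csv"), row.names = FALSE)
    jsonlite::write_json(list(model = fx$model, scenario = fx$scenario,
                              theta_true = fx$theta_true, seed = seed),
                         file.path(out_dir, "meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  fx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured ABC prediction experiment
#'
#' End-to-end pipeline: fixture generation (or user data), pilot weighting,
#' threshold calibration, sampling, predictive summarization and
#' serialization.  Deterministic given the seed; every resolved setting is
#' echoed to `meta.json` in the output directory.
#'
#' @param config a list (or path to a YAML/JSON file) with entries `model`
#'   ("ar1", "mg1" or "lv"), `scenario`, `mode` ("P", "F" or "L"), `summary`
#'   ("s0"/"s1" for mg1/lv; "s1"/"s2"/"s3" for ar1), `sampler` ("mcmc",
#'   "rejection" or "importance"), `iterations`, `burn_in`, `accept_rate`,
#'   `h_tilde`, `seed`, and optional preset `"desk"` or `"paper"`.
#' @param out_dir output directory (created); `NULL` to skip serialization.
#' @return list with the fixture, the sample set, the predictive summary and
#'   the resolved metadata.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  preset <- config$preset %||% "desk"
  defaults <- if (preset == "paper") {
    list(iterations = 2e6, burn_in = 1e4, accept_rate = 0.02)
  } else {
    list(iterations = 1e5, burn_in = 1e3, accept_rate = 0.02)
  }
  config$iterations <- config$iterations %||% defaults$iterations
  config$burn_in <- config$burn_in %||% defaults$burn_in
  config$accept_rate <- config$accept_rate %||% defaults$accept_rate
  seed <- config$seed %||% 1L
  res <- switch(config$model,
                ar1 = run_ar1_experiment(config, seed),
                mg1 = run_mg1_experiment(config, seed),
                lv = run_lv_experiment(config, seed),
                stop("unknown model: ", config$model))
  res$meta <- c(list(preset = preset, seed = seed), res$meta)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    samples_df <- as.data.frame(res$samples$theta)
    if (!is.null(res$samples$ytilde)) {
      yt <- as.data.frame(res$samples$ytilde)
      names(yt) <- paste0("ytilde", seq_len(ncol(yt)))
      samples_df <- cbind(samples_df, yt)
    }
    samples_df$weight <- res$samples$weights
    samples_df$discrepancy <- res$samples$discrepancy
    utils::write.csv(samples_df, file.path(out_dir, "samples.csv"),
                     row.names = FALSE)
    utils::write.csv(res$summary, file.path(out_dir, "predictive_summary.csv"),
                     row.names = FALSE)
    meta <- res$meta
    meta$acceptance_rate <- res$samples$acceptance_rate
    meta$ess <- res$samples$ess
    jsonlite::write_json(meta, file.path(out_dir, "meta.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

run_ar1_experiment <- function(config, seed) {
  fx <- generate_fixture("ar1", seed = child_seed(seed, 50L))
  model <- ar1_model(phi = fx$settings$phi, sigma2 = fx$settings$sigma2,
                     n = fx$settings$n, n_future = fx$settings$n_future)
  prior <- ar1_flat_prior()
  variant <- config$summary %||% "s1"
  summary_fn <- function(y) ar1_summaries(y, fx$settings$phi, variant)
  disc <- discrepancy_spec("linf")
  cfg <- mcmc_config(iterations = config$iterations, burn_in = config$burn_in,
                     proposal_scale = 0.5,
                     target_accept = config$accept_rate %||% 0.1)
  tuned <- tune_mcmc_threshold(model, prior, summary_fn, disc,
                               kernel_spec("uniform", 1), cfg, fx$y_obs,
                               seed = child_seed(seed, 51L),
                               rate = config$accept_rate %||% 0.1,
                               n_pilot = 2000)
  mode <- config$mode %||% "P"
  target <- prediction_target(if (mode == "F") "ABC_F" else "ABC_P")
  run <- abc_mcmc(model, prior, summary_fn, disc, tuned$kernel, cfg,
                  fx$y_obs, seed = child_seed(seed, 52L), target = target)
  if (mode == "F") run <- abc_f_predict(run, model, fx$y_obs,
                                        seed = child_seed(seed, 53L))
  summ <- summarize_predictive(run, truth = fx$truth)
  list(fixture = fx, samples = run, summary = summ,
       meta = list(model = "ar1", mode = mode, summary = variant,
                   h = tuned$kernel$h, realized_rate = run$acceptance_rate))
}

run_mg1_experiment <- function(config, seed) {
  scenario <- config$scenario %||% "varying"
  fx <- generate_fixture("mg1", seed = child_seed(seed, 50L),
                         scenario = scenario)
  n <- fx$settings$n; ntilde <- fx$settings$ntilde
  model <- mg1_model(n = n, ntilde = ntilde)
  prior <- mg1_prior(fx$y_obs)
  variant <- config$summary %||% "s1"
  summary_fn <- function(y) mg1_summaries(y, variant, y_obs_ref = fx$y_obs)
  disc <- estimate_summary_weights(model, fx$theta_true,
                                   function(y) mg1_summaries(y, "s0"),
                                   n_pilot = 1000, method = "cov",
                                   seed = child_seed(seed, 54L))
  h_tilde <- config$h_tilde %||% (if (scenario == "growing") 7 else 5)
  kernel <- if (variant == "s1") {
    product_kernel_spec(partition = list(bar = 1:5, tilde = 6:8),
                        norm_bar = disc,
                        norm_tilde = discrepancy_spec("linf"),
                        h_bar = Inf, h_tilde = h_tilde)
  } else kernel_spec("uniform", Inf)
  cfg <- mcmc_config(iterations = config$iterations, burn_in = config$burn_in,
                     proposal_scale = c(0.3, 0.5, 0.02),
                     target_accept = config$accept_rate)
  tuned <- tune_mcmc_threshold(model, prior, summary_fn, disc, kernel, cfg,
                               fx$y_obs, seed = child_seed(seed, 51L),
                               rate = config$accept_rate,
                               n_pilot = config$n_pilot %||% 5000,
                               pilot_iterations = config$pilot_iterations %||% 2e4,
                               max_retune = config$max_retune %||% 2L)
  mode <- config$mode %||% "P"
  target <- prediction_target(if (mode == "L") "ABC_L" else "ABC_P")
  run <- abc_mcmc(model, prior, summary_fn, disc, tuned$kernel, cfg,
                  fx$y_obs, seed = child_seed(seed, 52L), target = target)
  summ <- summarize_predictive(run, truth = fx$truth)
  list(fixture = fx, samples = run, summary = summ,
       meta = list(model = "mg1", scenario = scenario, mode = mode,
                   summary = variant, h_tilde = h_tilde,
                   realized_rate = run$acceptance_rate))
}

run_lv_experiment <- function(config, seed) {
  scenario <- config$scenario %||% "predict_case1"
  fx <- generate_fixture("lv", seed = child_seed(seed, 50L),
                         scenario = scenario)
  scheme <- fx$settings$scheme
  model <- lv_model(scheme)
  prior <- lv_prior()
  variant <- config$summary %||% "s1"
  summary_fn <- lv_summary_fn(scheme, variant)
  part <- lv_partition(scheme, fx$y_obs)
  bar_fn <- lv_summary_fn(scheme, "s0")
  disc <- estimate_summary_weights(model, fx$theta_true, bar_fn,
                                   n_pilot = config$n_pilot_w %||% 500,
                                   method = "mad",
                                   seed = child_seed(seed, 54L))
  h_tilde <- config$h_tilde %||% (if (scenario == "predict_case2") 30 else 50)
  kernel <- if (variant == "s1") {
    product_kernel_spec(partition = part, norm_bar = disc,
                        norm_tilde = discrepancy_spec("linf"),
                        h_bar = Inf, h_tilde = h_tilde)
  } else kernel_spec("uniform", Inf)
  cfg <- mcmc_config(iterations = config$iterations, burn_in = config$burn_in,
                     proposal_scale = 0.15,
                     target_accept = config$accept_rate)
  mode <- config$mode %||% "P"
  deferred <- mode == "P" && scenario != "missing_data"
  target <- prediction_target(switch(mode, P = "ABC_P", L = "ABC_L",
                                     F = "ABC_F"),
                              deferred = deferred)
  # independent chain seed streams per mode/summary so that method
  # comparisons on a shared fixture are not seed-coupled
  run_stream <- 60L + 4L * match(mode, c("P", "F", "L")) +
    as.integer(variant == "s1")
  tuned <- tune_mcmc_threshold(model, prior,
                               if (variant == "s1") summary_fn else bar_fn,
                               disc, kernel, cfg, fx$y_obs,
                               seed = child_seed(seed, 51L),
                               rate = config$accept_rate,
                               n_pilot = config$n_pilot %||% 2000,
                               pilot_iterations = config$pilot_iterations %||% 1e4,
                               max_retune = config$max_retune %||% 2L)
  run <- abc_mcmc(model, prior,
                  if (variant == "s1") summary_fn else bar_fn,
                  disc, tuned$kernel, cfg, fx$y_obs,
                  seed = child_seed(seed, run_stream), target = target)
  n_pred <- config$n_pred %||% 1000
  if (mode == "F") {
    keep <- thin_indices(length(run), n_pred)
    run <- subset_samples(run, keep)
    run <- abc_f_predict(run, model, fx$y_obs,
                         seed = child_seed(seed, run_stream + 40L))
  } else if (deferred) {
    run <- deferred_prediction(run, model,
                               which = thin_indices(length(run), n_pred),
                               seed = child_seed(seed, run_stream + 40L))
  }
  summ <- summarize_predictive(run, truth = fx$truth)
  list(fixture = fx, samples = run, summary = summ,
       meta = list(model = "lv", scenario = scenario, mode = mode,
                   summary = variant, h_tilde = h_tilde,
                   realized_rate = run$acceptance_rate,
                   mae = attr(summ, "mae")))
}

thin_indices <- function(m, k) {
  if (m <= k) seq_len(m) else unique(round(seq(1, m, length.out = k)))
}

subset_samples <- function(run, idx) {
  out <- run
  out$theta <- run$theta[idx, , drop = FALSE]
  if (!is.null(run$ytilde)) out$ytilde <- run$ytilde[idx, , drop = FALSE]
  if (!is.null(run$v)) out$v <- run$v[idx, , drop = FALSE]
  out$discrepancy <- run$discrepancy[idx]
  ne <- normalize_and_ess(run$weights[idx])
  out$weights <- ne$weights
  out$ess <- ne$ess
  out
}
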