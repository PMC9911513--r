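#' Stochastic Lotka-Volterra parameters
#'
#' Markov jump process for a prey population \eqn{y^1_t} and predator
#' population \eqn{y^2_t} with reactions prey birth (rate
#' \eqn{\theta_1 w_1}), predation (\eqn{\theta_2 w_1 w_2}; prey -1, predator
#' +1) and predator death (\eqn{\theta_3 w_2}).  The total jump rate is
#' \eqn{\gamma_\theta(w) = \theta_1 w_1 + \theta_2 w_1 w_2 + \theta_3 w_2}.
#'
#' @param theta1 prey birth rate (>= 0).
#' @param theta2 predation rate (>= 0).
#' @param theta3 predator death rate (>= 0; zero rates give degenerate
#'   sub-processes such as the pure-birth prey process).
#' @param y0 initial (prey, predator) counts (nonnegative integers).
#' @export
lv_params <- function(theta1 = 1, theta2 = 0.005, theta3 = 0.6,
                      y0 = c(100L, 50L)) {
  stopifnot(theta1 >= 0, theta2 >= 0, theta3 >= 0, length(y0) == 2,
            all(y0 >= 0), all(y0 == round(y0)))
  structure(list(theta = c(theta1, theta2, theta3), y0 = as.integer(y0)),
            class = "lv_params")
}

#' Exact Gillespie simulation of the predator-prey process
#'
#' Event-by-event stochastic simulation: exponential waiting times with rate
#' \eqn{\gamma_\theta(w)}, event type proportional to the three reaction
#' propensities, absorbing when \eqn{\gamma_\theta(w) = 0}.  Grid states are
#' the exact state carried forward to each grid time.  Trajectories that hit
#' `event_cap` events or a population above `pop_cap` are truncated with the
#' last state carried forward and flagged `capped` (predator extinction makes
#' the prey population explode exponentially, so a cap is needed to keep
#' prior-wide sampling total).
#'
#' @param params an [lv_params()].
#' @param t_grid nondecreasing grid times (starting at or after 0).
#' @param seed integer seed.
#' @param event_cap maximum number of events (default 1e7).
#' @param pop_cap maximum population per species (default 1e6).
#' @param y_start optional starting state overriding `params$y0` (used for
#'   conditional continuation from an observed/simulated state).
#' @param return_path also return the exact event path (for small
#'   trajectories only).
#' @return list with `times`, `states` (2 x length(t_grid): prey row 1,
#'   predator row 2), `capped`, `n_events`, and the event path if requested.
#' @export
lv_gillespie <- function(params, t_grid, seed, event_cap = 1e7,
                         pop_cap = 1e6, y_start = NULL, return_path = FALSE) {
  stopifnot(inherits(params, "lv_params"), event_cap > 0,
            !is.unsorted(t_grid))
  y0 <- if (is.null(y_start)) params$y0 else as.integer(round(y_start))
  out <- lv_gillespie_cpp(params$theta[1], params$theta[2], params$theta[3],
                          y0[1], y0[2], as.numeric(t_grid),
                          as.integer(seed), event_cap, pop_cap, return_path)
  res <- list(times = as.numeric(t_grid), states = out$grid,
              capped = out$capped, n_events = out$n_events)
  if (return_path) {
    res$path <- data.frame(t = out$path_t, y1 = out$path_y1, y2 = out$path_y2)
  }
  res
}

#' Observation schemes for the predator-prey experiments
#'
#' \describe{
#'   \item{predict_case1}{both populations observed at 81 equidistant times
#'     on \eqn{[0, 24]} (spacing \eqn{\delta = 0.3}, endpoints included);
#'     predict both populations on \eqn{(24, 45]}.}
#'   \item{predict_case2}{as case 1 but only the prey population is
#'     observed.}
#'   \item{missing_data}{both populations observed at 51 equidistant times on
#'     each of \eqn{[0, 15]} and \eqn{[36, 51]}; estimate both populations on
#'     the missing interval \eqn{(15, 36)}.}
#' }
#' The prediction grid uses the same spacing \eqn{\delta = 0.3} as the
#' observation grid.
#'
#' @param scenario one of "predict_case1", "predict_case2", "missing_data".
#' @export
lv_scheme <- function(scenario = c("predict_case1", "predict_case2",
                                   "missing_data")) {
  scenario <- match.arg(scenario)
  delta <- 0.3
  if (scenario %in% c("predict_case1", "predict_case2")) {
    tau1 <- 24; tau2 <- 45
    obs <- seq(0, tau1, by = delta)          # 81 points
    pred <- seq(tau1 + delta, tau2, by = delta)  # 70 points
    full <- c(obs, pred)
    list(scenario = scenario, delta = delta, tau1 = tau1, tau2 = tau2,
         full = full, obs_idx = seq_along(obs),
         pred_idx = length(obs) + seq_along(pred),
         components = if (scenario == "predict_case1") "both" else "prey")
  } else {
    tau1 <- 15; tau2 <- 36; tau3 <- 51
    full <- seq(0, tau3, by = delta)         # 171 points
    w1 <- which(full <= tau1 + 1e-9)         # 51 points
    w2 <- which(full >= tau2 - 1e-9)         # 51 points
    mid <- which(full > tau1 + 1e-9 & full < tau2 - 1e-9)  # 69 points
    list(scenario = scenario, delta = delta, tau1 = tau1, tau2 = tau2,
         tau3 = tau3, full = full, obs_idx = c(w1, w2), pred_idx = mid,
         w1_idx = w1, w2_idx = w2, components = "both")
  }
}

# biased (1/n) autocorrelation at a lag; errors on constant series
acf_lag <- function(x, lag) {
  n <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) stop("autocorrelation undefined for a constant series")
  sum(xc[seq_len(n - lag)] * xc[seq_len(n - lag) + lag]) / denom
}

series_stats <- function(x) {
  c(mean = mean(x), sd = stats::sd(x), acf1 = acf_lag(x, 1L),
    acf2 = acf_lag(x, 2L))
}

# condition-free variant for the samplers' hot loop: degenerate series give
# NA coordinates (rejected draws) instead of signalling an error, which is
# far cheaper when a chain visits extinct-population regions
series_stats_quiet <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) return(rep(NA_real_, 4))
  c(mean(x), sqrt(denom / (n - 1)),
    sum(xc[seq_len(n - 1)] * xc[seq_len(n - 1) + 1L]) / denom,
    sum(xc[seq_len(n - 2)] * xc[seq_len(n - 2) + 2L]) / denom)
}

lv_summaries_quiet <- function(y, scheme) {
  if (scheme$scenario == "predict_case1") {
    G <- length(scheme$obs_idx)
    prey <- y[seq_len(G)]; pred <- y[G + seq_len(G)]
    sp <- series_stats_quiet(prey); sq <- series_stats_quiet(pred)
    cc <- if (anyNA(c(sp, sq))) NA_real_ else stats::cor(prey, pred)
    c(sp, sq, cc, prey[G], pred[G])
  } else if (scheme$scenario == "predict_case2") {
    G <- length(scheme$obs_idx)
    prey <- y[seq_len(G)]
    c(series_stats_quiet(prey), prey[G - 0:5])
  } else {
    s <- lv_summaries(y, scheme)  # no autocorrelations involved
    unname(s$value)
  }
}

#' Summary statistics for the predator-prey experiments
#'
#' Returns the full summary vector together with its parameter-block /
#' prediction-block partition, per scenario:
#' \describe{
#'   \item{predict_case1}{\eqn{\bar s \in R^9}: mean, standard deviation and
#'     the first two autocorrelations of each population plus their lag-0
#'     cross-correlation; \eqn{\tilde s = y_{\tau_1} \in R^2}.}
#'   \item{predict_case2}{\eqn{\bar s \in R^4}: the same four statistics of
#'     the prey series; \eqn{\tilde s = (y^1_{\tau_1 - i\delta})_{i=0..5}
#'     \in R^6}.}
#'   \item{missing_data}{\eqn{\bar s \in R^8}: mean and standard deviation of
#'     both populations over each observed window; \eqn{\tilde s =
#'     (y_{\tau_1}, y_{\tau_2}) \in R^4}.}
#' }
#' Constant series raise an error naming the undefined statistic.
#'
#' @param y observed-grid data in the model's flattened layout (see
#'   [lv_model()]).
#' @param scheme an [lv_scheme()].
#' @export
lv_summaries <- function(y, scheme) {
  if (scheme$scenario == "predict_case1") {
    G <- length(scheme$obs_idx)
    prey <- y[seq_len(G)]; pred <- y[G + seq_len(G)]
    sp <- series_stats(prey); sq <- series_stats(pred)
    cc <- stats::cor(prey, pred)
    if (is.na(cc)) stop("cross-correlation undefined for a constant series")
    s_bar <- c(prey = sp, pred = sq, cross = cc)
    s_tilde <- c(prey_tau1 = prey[G], pred_tau1 = pred[G])
  } else if (scheme$scenario == "predict_case2") {
    G <- length(scheme$obs_idx)
    prey <- y[seq_len(G)]
    s_bar <- c(prey = series_stats(prey))
    s_tilde <- stats::setNames(prey[G - 0:5], paste0("prey_lag", 0:5))
  } else {
    k <- length(scheme$w1_idx)
    prey1 <- y[seq_len(k)]; pred1 <- y[k + seq_len(k)]
    prey2 <- y[2 * k + seq_len(k)]; pred2 <- y[3 * k + seq_len(k)]
    s_bar <- c(w1_prey_mean = mean(prey1), w1_prey_sd = stats::sd(prey1),
               w1_pred_mean = mean(pred1), w1_pred_sd = stats::sd(pred1),
               w2_prey_mean = mean(prey2), w2_prey_sd = stats::sd(prey2),
               w2_pred_mean = mean(pred2), w2_pred_sd = stats::sd(pred2))
    s_tilde <- c(prey_tau1 = prey1[k], pred_tau1 = pred1[k],
                 prey_tau2 = prey2[1], pred_tau2 = pred2[1])
  }
  list(value = c(s_bar, s_tilde),
       partition = list(bar = seq_along(s_bar),
                        tilde = length(s_bar) + seq_along(s_tilde)))
}

#' Summary function and partition for a scenario
#'
#' Convenience wrappers returning the plain summary function used by the
#' samplers, and the block partition for the two-block product kernel.  With
#' `variant = "s0"` only the parameter-informative block is used (the
#' partition then has an empty prediction block).
#'
#' @param scheme an [lv_scheme()].
#' @param variant "s1" (partitioned, with prediction block) or "s0"
#'   (baseline block only).
#' @export
lv_summary_fn <- function(scheme, variant = c("s1", "s0")) {
  variant <- match.arg(variant)
  force(scheme)
  n_bar <- switch(scheme$scenario, predict_case1 = 9L, predict_case2 = 4L, 8L)
  if (variant == "s1") {
    function(y) lv_summaries_quiet(y, scheme)
  } else {
    function(y) lv_summaries_quiet(y, scheme)[seq_len(n_bar)]
  }
}

#' @rdname lv_summary_fn
#' @param y_example example data vector (used to size the partition).
#' @export
lv_partition <- function(scheme, y_example) {
  lv_summaries(y_example, scheme)$partition
}

#' Log-uniform prior for the predator-prey rates
#'
#' \eqn{(\log\theta_1, \log\theta_2, \log\theta_3) \sim U([-6, 2]^3)};
#' inference runs on the log scale.
#' @export
lv_prior <- function() {
  uniform_prior(lower = rep(-6, 3), upper = rep(2, 3), log_scale = TRUE,
                names = c("theta1", "theta2", "theta3"))
}

#' Predator-prey simulator model for the ABC samplers
#'
#' Joint simulation runs the Gillespie algorithm over the scenario's full
#' grid; the observed-part layout is `c(prey, predator)` per observed grid
#' time (case 1 / missing data) or the prey series alone (case 2), and the
#' future block is `c(prey, predator)` over the prediction grid.  The stored
#' latent `v` is the full simulated state at \eqn{\tau_1}; in case 2 the
#' ABC-L prediction step replaces its prey component by the observed value,
#' while deferred ABC-P continues from the simulated state.  With
#' `predict = FALSE` the simulation stops at \eqn{\tau_1}.
#' ABC-F (conditional prediction from the observed state) is available only
#' in case 1 where the state at \eqn{\tau_1} is fully observed.
#'
#' @param scheme an [lv_scheme()].
#' @param y0 initial counts.
#' @param event_cap,pop_cap simulation caps (see [lv_gillespie()]).
#' @export
lv_model <- function(scheme, y0 = c(100L, 50L), event_cap = 1e7,
                     pop_cap = 1e6) {
  force(scheme); force(y0); force(event_cap); force(pop_cap)
  obs_t <- scheme$full[scheme$obs_idx]
  pred_t <- scheme$full[scheme$pred_idx]
  pack_obs <- function(states) {
    if (scheme$scenario == "predict_case1") {
      c(states[1, ], states[2, ])
    } else if (scheme$scenario == "predict_case2") {
      states[1, ]
    } else {
      k <- length(scheme$w1_idx)
      c(states[1, seq_len(k)], states[2, seq_len(k)],
        states[1, k + seq_len(k)], states[2, k + seq_len(k)])
    }
  }
  simulate_joint <- function(theta, seed, predict = TRUE, ...) {
    pars <- lv_params(theta[1], theta[2], theta[3], y0 = y0)
    if (scheme$scenario == "missing_data") {
      # future block sits between the observed windows: always simulate fully
      tr <- lv_gillespie(pars, scheme$full, seed, event_cap, pop_cap)
      obs <- tr$states[, scheme$obs_idx, drop = FALSE]
      return(list(y = pack_obs(obs),
                  ytilde = c(tr$states[1, scheme$pred_idx],
                             tr$states[2, scheme$pred_idx]),
                  v = c(tr$states[, max(scheme$w1_idx)])))
    }
    t_sim <- if (predict) scheme$full else obs_t
    tr <- lv_gillespie(pars, t_sim, seed, event_cap, pop_cap)
    G <- length(obs_t)
    state_tau1 <- tr$states[, G]
    list(y = pack_obs(tr$states[, seq_len(G), drop = FALSE]),
         ytilde = if (predict) c(tr$states[1, G + seq_along(pred_t)],
                                 tr$states[2, G + seq_along(pred_t)]) else NULL,
         v = state_tau1)
  }
  continue_from <- function(theta, state, seed) {
    pars <- lv_params(theta[1], theta[2], theta[3], y0 = y0)
    tr <- lv_gillespie(pars, pred_t - scheme$tau1, seed, event_cap, pop_cap,
                       y_start = state)
    c(tr$states[1, ], tr$states[2, ])
  }
  cond_pred <- NULL
  latent_cond_pred <- NULL
  caps <- "JOINT"
  if (scheme$scenario == "predict_case1") {
    cond_pred <- function(theta, y, seed) {
      G <- length(obs_t)
      continue_from(theta, c(y[G], y[2 * G]), seed)
    }
    latent_cond_pred <- function(theta, y, v, seed) {
      continue_from(theta, v, seed)
    }
    caps <- c("JOINT", "JOINT_LATENT", "COND_PRED", "LATENT_COND_PRED")
  } else if (scheme$scenario == "predict_case2") {
    latent_cond_pred <- function(theta, y, v, seed) {
      # ABC-L conditions on the *observed* prey value at tau1 when the series
      # is supplied; deferred ABC-P continues from the simulated state in v
      prey <- if (!is.null(y) && length(y) > 0) y[length(y)] else v[1]
      continue_from(theta, c(prey, v[2]), seed)
    }
    caps <- c("JOINT", "JOINT_LATENT", "LATENT_COND_PRED")
  }
  simulator_model("lotka_volterra", capabilities = caps,
                  simulate_joint = simulate_joint, cond_pred = cond_pred,
                  latent_cond_pred = latent_cond_pred,
                  theta_names = c("theta1", "theta2", "theta3"),
                  log_scale = rep(TRUE, 3),
                  extra = list(scheme = scheme, y0 = y0))
}

#' Ideal (true-parameter) predictive baselines
#'
#' The unattainable reference predictive using the true parameter and the
#' exact latent state:
#' \describe{
#'   \item{predict_case1}{\eqn{\pi(\tilde y \mid y_{\tau_1}, \theta_{true})}
#'     simulated directly from the observed state.}
#'   \item{predict_case2}{rejection form: simulate \eqn{(\tilde y, z)} at
#'     \eqn{\theta_{true}} and accept when the prey series matches the last
#'     six observed values within `tol` in sup-norm.}
#'   \item{missing_data}{simulate forward from the observed \eqn{y_{\tau_1}}
#'     and accept when the state at \eqn{\tau_2} matches the observed one
#'     within `tol` in sup-norm (`tol = 0` gives exact conditional samples).}
#' }
#'
#' @param params_true an [lv_params()] at the true parameter.
#' @param y_obs observed data in the scenario layout.
#' @param scheme an [lv_scheme()].
#' @param tol acceptance tolerance (sup-norm; `Inf` accepts everything).
#' @param m number of simulations.
#' @param seed integer seed.
#' @return list with `ytilde` (accepted draws, rows =
#'   `c(prey, predator)` over the prediction grid) and `acceptance_rate`.
#' @export
lv_ideal_predictive <- function(params_true, y_obs, scheme, tol, m, seed) {
  pred_t <- scheme$full[scheme$pred_idx]
  if (scheme$scenario == "predict_case1") {
    G <- length(scheme$obs_idx)
    state <- c(y_obs[G], y_obs[2 * G])
    draws <- t(vapply(seq_len(m), function(i) {
      tr <- lv_gillespie(params_true, pred_t - scheme$tau1,
                         child_seed(seed, 40L, i), y_start = state)
      c(tr$states[1, ], tr$states[2, ])
    }, numeric(2 * length(pred_t))))
    return(list(ytilde = draws, acceptance_rate = 1))
  }
  if (scheme$scenario == "predict_case2") {
    G <- length(scheme$obs_idx)
    ref <- y_obs[G - 0:5]
    keep <- list()
    n_acc <- 0L
    for (i in seq_len(m)) {
      tr <- lv_gillespie(params_true, scheme$full, child_seed(seed, 41L, i))
      z_ref <- tr$states[1, G - 0:5]
      if (max(abs(z_ref - ref)) <= tol) {
        n_acc <- n_acc + 1L
        keep[[n_acc]] <- c(tr$states[1, scheme$pred_idx],
                           tr$states[2, scheme$pred_idx])
      }
    }
    if (n_acc == 0L) stop("no draws accepted by the ideal-predictive filter")
    return(list(ytilde = do.call(rbind, keep), acceptance_rate = n_acc / m))
  }
  # missing data: forward from observed state at tau1, match state at tau2
  k <- length(scheme$w1_idx)
  state_tau1 <- c(y_obs[k], y_obs[2 * k])
  y_tau2 <- c(y_obs[2 * k + 1], y_obs[3 * k + 1])
  t_fwd <- c(scheme$full[scheme$pred_idx], scheme$tau2) - scheme$tau1
  keep <- list()
  n_acc <- 0L
  for (i in seq_len(m)) {
    tr <- lv_gillespie(params_true, t_fwd, child_seed(seed, 42L, i),
                       y_start = state_tau1)
    J <- length(t_fwd)
    z_tau2 <- tr$states[, J]
    if (max(abs(z_tau2 - y_tau2)) <= tol) {
      n_acc <- n_acc + 1L
      keep[[n_acc]] <- c(tr$states[1, -J], tr$states[2, -J])
    }
  }
  if (n_acc == 0L) stop("no draws accepted by the ideal-predictive filter")
  list(ytilde = do.call(rbind, keep), acceptance_rate = n_acc / m)
}
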