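#' Prediction target specification
#'
#' Declares which predictive ABC approximation a sampler run targets and
#' checks it against the model's declared capabilities:
#' \describe{
#'   \item{POSTERIOR}{standard ABC for the parameters only (needs JOINT).}
#'   \item{ABC_F}{standard ABC for the parameters; prediction is done
#'     afterwards with [abc_f_predict()] (needs JOINT + COND_PRED).}
#'   \item{ABC_P}{joint target over \eqn{(\tilde y, \theta)}: the future data
#'     are simulated alongside the pseudo-data and accepted with them (needs
#'     JOINT; with `deferred = TRUE`, JOINT_LATENT + LATENT_COND_PRED).}
#'   \item{ABC_L}{joint ABC target over \eqn{(v, \theta)}; prediction draws
#'     \eqn{\tilde y \sim \pi(\tilde y \mid y, v, \theta)} for retained draws
#'     (needs JOINT_LATENT + LATENT_COND_PRED).}
#' }
#'
#' @param mode one of "POSTERIOR", "ABC_F", "ABC_P", "ABC_L".
#' @param deferred logical; for ABC_P, simulate the future data only for
#'   retained (positive-weight, post-burn-in) draws via the latent-variable
#'   factorization instead of jointly with every proposal.
#' @export
prediction_target <- function(mode = c("ABC_P", "ABC_F", "ABC_L", "POSTERIOR"),
                              deferred = FALSE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, deferred = deferred), class = "abc_target")
}

check_target <- function(model, target) {
  stopifnot(inherits(target, "abc_target"))
  switch(target$mode,
         POSTERIOR = require_capability(model, "JOINT", "standard ABC"),
         ABC_F = {
           require_capability(model, "JOINT", "ABC-F")
           require_capability(model, "COND_PRED", "ABC-F prediction")
         },
         ABC_P = {
           require_capability(model, "JOINT", "ABC-P")
           if (target$deferred) {
             require_capability(model, "JOINT_LATENT", "deferred ABC-P")
             require_capability(model, "LATENT_COND_PRED", "deferred ABC-P")
           }
         },
         ABC_L = {
           require_capability(model, "JOINT_LATENT", "ABC-L")
           require_capability(model, "LATENT_COND_PRED", "ABC-L prediction")
         })
  invisible(TRUE)
}

#' Two-block product kernel (uniform on each block)
#'
#' Wraps [product_kernel_accept()] as a kernel object usable by the samplers.
#' The parameter-informative block is compared under `norm_bar` with
#' threshold `h_bar` and the prediction-informative block under `norm_tilde`
#' with threshold `h_tilde`.
#'
#' @inheritParams product_kernel_accept
#' @export
product_kernel_spec <- function(partition, norm_bar, norm_tilde, h_bar, h_tilde) {
  stopifnot(h_bar >= 0, h_tilde >= 0)
  structure(list(partition = partition, norm_bar = norm_bar,
                 norm_tilde = norm_tilde, h_bar = h_bar, h_tilde = h_tilde),
            class = "abc_product_kernel")
}

#' @export
print.abc_product_kernel <- function(x, ...) {
  cat(sprintf("Product uniform kernel: h_bar = %g (%d coords), h_tilde = %g (%d coords)\n",
              x$h_bar, length(x$partition$bar), x$h_tilde,
              length(x$partition$tilde)))
  invisible(x)
}

# Acceptance weight and diagnostic discrepancy for one simulated summary.
# Returns c(weight, discrepancy); failed/NA summaries get weight 0.
kernel_weight <- function(kernel, discrepancy, s_y, s_z) {
  if (is.null(s_z) || anyNA(s_z)) return(c(0, Inf))
  if (inherits(kernel, "abc_product_kernel")) {
    d_bar <- compute_discrepancy(kernel$norm_bar, s_y[kernel$partition$bar],
                                 s_z[kernel$partition$bar])
    w <- product_kernel_accept(s_y, s_z, kernel$partition, kernel$norm_bar,
                               kernel$norm_tilde, kernel$h_bar, kernel$h_tilde)
    c(w, d_bar)
  } else {
    d <- compute_discrepancy(discrepancy, s_y, s_z)
    c(evaluate_kernel(kernel, d), d)
  }
}

kernel_is_uniform <- function(kernel) {
  inherits(kernel, "abc_product_kernel") ||
    (inherits(kernel, "abc_kernel") && kernel$kind == "uniform")
}

# relative excess over a uniform acceptance region; <= 1 means accept
kernel_score <- function(kernel, discrepancy, s_y, s_z) {
  if (is.null(s_z)) return(Inf)
  if (inherits(kernel, "abc_product_kernel")) {
    d_bar <- compute_discrepancy(kernel$norm_bar, s_y[kernel$partition$bar],
                                 s_z[kernel$partition$bar])
    d_til <- compute_discrepancy(kernel$norm_tilde,
                                 s_y[kernel$partition$tilde],
                                 s_z[kernel$partition$tilde])
    max(d_bar / max(kernel$h_bar, .Machine$double.eps),
        d_til / max(kernel$h_tilde, .Machine$double.eps))
  } else {
    compute_discrepancy(discrepancy, s_y, s_z) /
      max(kernel$h, .Machine$double.eps)
  }
}

# Evaluate a summary function defensively: simulation regions of the prior can
# produce degenerate data (e.g. constant series) for which some statistics are
# undefined; such draws are treated as rejected rather than aborting the run.
safe_summary <- function(summary_fn, z) {
  s <- tryCatch(summary_fn(z), error = function(e) NULL)
  if (is.null(s) || anyNA(s)) NULL else as.numeric(s)
}

zero_acceptance_error <- function(dvals) {
  q <- stats::quantile(dvals[is.finite(dvals)],
                       probs = c(0, 0.01, 0.05, 0.25),
                       na.rm = TRUE)
  stop("no draws accepted; smallest discrepancies seen: ",
       paste(sprintf("%s=%.4g", names(q), q), collapse = ", "),
       call. = FALSE)
}

#' ABC rejection sampler
#'
#' Basic rejection ABC with a uniform (or product-uniform) kernel: draw
#' \eqn{\theta^{(i)}} from the prior, simulate pseudo-data \eqn{z^{(i)}}
#' (jointly with future data \eqn{\tilde y^{(i)}} for ABC-P, and with latent
#' variables \eqn{v^{(i)}} for ABC-L), and accept when the summary
#' discrepancy is at most the threshold (boundary ties accepted).  Accepted
#' draws are i.i.d. from the corresponding augmented ABC target.
#'
#' @param model an [simulator_model()].
#' @param prior an [prior_spec()].
#' @param summary_fn function mapping a data set to its summary vector.
#' @param discrepancy an [discrepancy_spec()] (ignored for a product kernel).
#' @param kernel a uniform [kernel_spec()] or [product_kernel_spec()].
#' @param y_obs observed data (summarized internally).
#' @param m number of proposals.
#' @param seed integer root seed.
#' @param target an [prediction_target()].
#' @param ... passed to the model's joint simulator.
#' @return an [weighted_samples()] object with equal weights on accepted draws.
#' @export
abc_rejection <- function(model, prior, summary_fn, discrepancy, kernel,
                          y_obs, m, seed, target = prediction_target("POSTERIOR"),
                          ...) {
  if (!kernel_is_uniform(kernel)) {
    stop("abc_rejection requires a uniform (or product-uniform) kernel; ",
         "use abc_importance for smooth kernels")
  }
  run_is_core(model, prior, proposal = NULL, summary_fn, discrepancy, kernel,
              y_obs, m, seed, target, rejection = TRUE, ...)
}

#' ABC self-normalized importance sampler
#'
#' Draws \eqn{\theta^{(i)} \sim q(\theta)}, simulates pseudo-data (and future
#' data / latents as required by the target), and attaches the unnormalized
#' weight \eqn{\tilde\omega^{(i)} = K_h(\Delta(s_y, s_z^{(i)}))\,
#' \pi(\theta^{(i)}) / q(\theta^{(i)})}; the intractable likelihood terms
#' cancel between target and proposal.  With a uniform kernel and
#' \eqn{q = \pi} this reduces to the rejection sampler.  For ABC-L the
#' prediction step runs only for positive-weight draws (two-stage form).
#'
#' @inheritParams abc_rejection
#' @param proposal an [prior_spec()]-like object used as proposal `q`; `NULL`
#'   means `q = prior`.
#' @export
abc_importance <- function(model, prior, proposal = NULL, summary_fn,
                           discrepancy, kernel, y_obs, m, seed,
                           target = prediction_target("POSTERIOR"), ...) {
  run_is_core(model, prior, proposal, summary_fn, discrepancy, kernel,
              y_obs, m, seed, target, rejection = FALSE, ...)
}

run_is_core <- function(model, prior, proposal, summary_fn, discrepancy,
                        kernel, y_obs, m, seed, target, rejection, ...) {
  check_target(model, target)
  q <- if (is.null(proposal)) prior else proposal
  s_y <- as.numeric(summary_fn(y_obs))
  theta <- q$sample(m, seed = child_seed(seed, 1L))
  needs_pred <- target$mode == "ABC_P" && !target$deferred
  needs_latent <- target$mode == "ABC_L" ||
    (target$mode == "ABC_P" && target$deferred)
  wts <- numeric(m)
  dvals <- rep(Inf, m)
  yt <- vector("list", m)
  vv <- vector("list", m)
  for (i in seq_len(m)) {
    th <- theta[i, ]
    lp <- prior$log_density(th)
    if (!is.finite(lp)) next
    lq <- if (is.null(proposal)) lp else q$log_density(th)
    if (!is.finite(lq)) {
      stop("proposal density is zero at a drawn parameter where the prior is positive")
    }
    sim <- simulate_joint(model, th, seed = child_seed(seed, 2L, i),
                          predict = needs_pred, ...)
    s_z <- safe_summary(summary_fn, sim$y)
    wd <- kernel_weight(kernel, discrepancy, s_y, s_z)
    dvals[i] <- wd[2]
    if (wd[1] == 0) next
    wts[i] <- wd[1] * exp(lp - lq)
    if (needs_pred) yt[[i]] <- sim$ytilde
    if (needs_latent) vv[[i]] <- sim$v
  }
  keep <- which(wts > 0)
  if (length(keep) == 0L) zero_acceptance_error(dvals)
  ytilde <- NULL
  v <- NULL
  if (needs_latent) v <- do.call(rbind, vv[keep])
  if (target$mode == "ABC_L") {
    # two-stage form: prediction only for positive-weight draws
    ytilde <- t(vapply(seq_along(keep), function(j) {
      i <- keep[j]
      as.numeric(model$latent_cond_pred(theta[i, ], y_obs, vv[[i]],
                                        seed = child_seed(seed, 3L, i)))
    }, FUN.VALUE = predict_template(model, theta[keep[1], ], y_obs, vv[[keep[1]]],
                                    seed = child_seed(seed, 3L, keep[1]))))
  } else if (needs_pred) {
    ytilde <- do.call(rbind, yt[keep])
  }
  weighted_samples(theta = theta[keep, , drop = FALSE], ytilde = ytilde, v = v,
                   weights = wts[keep], discrepancy = dvals[keep],
                   acceptance_rate = length(keep) / m,
                   mode = target$mode, seed = seed,
                   config = list(sampler = if (rejection) "rejection" else "importance",
                                 m = m))
}

predict_template <- function(model, th, y_obs, v, seed) {
  as.numeric(model$latent_cond_pred(th, y_obs, v, seed = seed)) * 0
}

#' MCMC configuration
#'
#' @param iterations total chain length `m`.
#' @param burn_in burn-in length (< `iterations`).
#' @param proposal_scale per-coordinate random-walk standard deviation on the
#'   inference scale (log scale for log-flagged coordinates); recycled.
#' @param thin keep every `thin`-th post-burn-in state.
#' @param adapt logical; during burn-in only, rescale the random walk to the
#'   chain's empirical spread (2.4 sd per coordinate / sqrt(p)), frozen
#'   afterwards so the invariant Metropolis-Hastings kernel is honored
#'   exactly post burn-in.  The *acceptance rate* is then governed by the
#'   threshold, which [tune_mcmc_threshold()] calibrates to the target.
#' @param target_accept target acceptance rate recorded for threshold
#'   calibration.
#' @param init_budget maximum number of prior draws used to locate an initial
#'   state with positive kernel weight.
#' @param max_store cap on stored post-burn-in records (thinning is raised if
#'   needed).
#' @export
mcmc_config <- function(iterations, burn_in = ceiling(iterations / 10),
                        proposal_scale = 0.1, thin = 1L, adapt = TRUE,
                        target_accept = 0.1, init_budget = 1e5,
                        max_store = 1e5) {
  stopifnot(burn_in < iterations, all(proposal_scale > 0), thin >= 1)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 proposal_scale = proposal_scale, thin = as.integer(thin),
                 adapt = adapt, target_accept = target_accept,
                 init_budget = init_budget, max_store = max_store),
            class = "abc_mcmc_config")
}

to_inference_scale <- function(model, theta) {
  ls <- model$log_scale
  if (is.null(ls) || !any(ls)) return(theta)
  theta[ls] <- log(theta[ls])
  theta
}

from_inference_scale <- function(model, u) {
  ls <- model$log_scale
  if (is.null(ls) || !any(ls)) return(u)
  u[ls] <- exp(u[ls])
  u
}

# log prior on the inference scale (includes the log-transform Jacobian)
log_prior_inference <- function(model, prior, u) {
  th <- from_inference_scale(model, u)
  lp <- prior$log_density(th)
  ls <- model$log_scale
  if (!is.null(ls) && any(ls) && is.finite(lp)) lp <- lp + sum(u[ls])
  lp
}

#' ABC-MCMC sampler for the (augmented) ABC targets
#'
#' Metropolis-Hastings chain on the augmented target
#' \eqn{\propto K_h(\Delta(s_y, s_z))\,\pi(\tilde y, s_z \mid \theta)\,
#' \pi(\theta)} with proposal \eqn{\pi(\tilde y^*, s_z^* \mid \theta^*)\,
#' q(\theta^* \mid \theta)}.  The acceptance probability reduces to
#' \deqn{\alpha = \min\{1, K_h(\Delta^*)\pi(\theta^*) q(\theta \mid \theta^*)
#' / [K_h(\Delta)\pi(\theta) q(\theta^* \mid \theta)]\}}
#' and does not depend on \eqn{\tilde y}; on rejection the full triple
#' \eqn{(\tilde y, z, \theta)} is repeated.  The default proposal is a
#' Gaussian random walk on the inference scale (symmetric, so the `q` ratio
#' cancels); a custom proposal with evaluable density may be supplied for
#' discrete or otherwise non-Euclidean parameter spaces.
#'
#' @inheritParams abc_rejection
#' @param config an [mcmc_config()].
#' @param proposal optional list with `sample(theta, seed)` and
#'   `log_density(to, from)` overriding the random walk.
#' @param init optional initial parameter value (natural scale); by default
#'   prior draws are tried until one has positive kernel weight.
#' @return an [weighted_samples()] with equal weights (correlated draws) and
#'   the realized post-burn-in acceptance rate.
#' @export
abc_mcmc <- function(model, prior, summary_fn, discrepancy, kernel, config,
                     y_obs, seed, target = prediction_target("POSTERIOR"),
                     proposal = NULL, init = NULL, ...) {
  check_target(model, target)
  stopifnot(inherits(config, "abc_mcmc_config"))
  s_y <- as.numeric(summary_fn(y_obs))
  needs_pred <- target$mode == "ABC_P" && !target$deferred
  needs_latent <- target$mode == "ABC_L" ||
    (target$mode == "ABC_P" && target$deferred)
  p <- prior$p

  # initial state: positive kernel weight and positive prior required
  init_state <- mcmc_init(model, prior, summary_fn, discrepancy, kernel, s_y,
                          seed, config$init_budget, init, needs_pred, ...)
  u <- to_inference_scale(model, init_state$theta)
  lp <- log_prior_inference(model, prior, u)
  kw <- init_state$kw
  cur <- init_state$sim
  cur_d <- init_state$d
  cur_score <- init_state$score
  uniform <- kernel_is_uniform(kernel)
  # burn-in threshold annealing: when no prior draw lands in the acceptance
  # region, start from the best-scoring state and shrink the threshold
  # inflation factor f multiplicatively toward 1, floored at the current
  # state's score so the chain state always stays inside the inflated
  # region; sampling starts only once f has reached 1 (exact target kernel)
  f <- if (uniform && cur_score > 1) 2 * cur_score else 1
  f_decay <- if (f > 1) (1 / f)^(1 / max(100L, floor(config$burn_in / 2))) else 1
  best_score <- cur_score

  m <- config$iterations
  burn <- config$burn_in
  # annealing may extend the effective burn-in (up to this deadline) when the
  # chain has not yet reached the exact acceptance region
  anneal_deadline <- burn + floor((m - burn) / 2)
  n_post <- m - burn
  thin <- max(config$thin, ceiling(n_post / config$max_store))
  n_keep <- floor(n_post / thin)
  theta_out <- matrix(NA_real_, n_keep, p)
  d_out <- numeric(n_keep)
  yt_out <- vector("list", n_keep)
  v_out <- vector("list", n_keep)
  prop_d <- numeric(m)  # proposed-state discrepancies (threshold retuning)

  scale <- rep(config$proposal_scale, length.out = p)
  scale0 <- scale
  # Welford accumulators for burn-in proposal-scale adaptation
  nw <- 0L; mw <- numeric(p); sw <- numeric(p)
  set.seed(child_seed(seed, 11L))
  eps <- matrix(stats::rnorm(m * p), m, p)
  uacc <- stats::runif(m)
  n_acc_post <- 0L
  n_post_seen <- 0L
  post_started <- FALSE
  kept <- 0L
  for (i in seq_len(m)) {
    if (is.null(proposal)) {
      u_star <- u + scale * eps[i, ]
      lq_ratio <- 0
    } else {
      th_star <- proposal$sample(from_inference_scale(model, u),
                                 seed = child_seed(seed, 12L, i))
      u_star <- to_inference_scale(model, th_star)
      lq_ratio <- proposal$log_density(from_inference_scale(model, u), th_star) -
        proposal$log_density(th_star, from_inference_scale(model, u))
    }
    lp_star <- log_prior_inference(model, prior, u_star)
    accept <- FALSE
    prop_d[i] <- Inf
    if (is.finite(lp_star)) {
      th_star_nat <- from_inference_scale(model, u_star)
      sim_star <- simulate_joint(model, th_star_nat,
                                 seed = child_seed(seed, 2L, i),
                                 predict = needs_pred, ...)
      s_z <- safe_summary(summary_fn, sim_star$y)
      wd <- kernel_weight(kernel, discrepancy, s_y, s_z)
      sc_star <- kernel_score(kernel, discrepancy, s_y, s_z)
      prop_d[i] <- wd[2]
      w_star <- if (uniform) as.numeric(sc_star <= f) else wd[1]
      if (w_star > 0) {
        log_alpha <- if (uniform) lp_star - lp + lq_ratio else
          log(w_star) - log(kw) + lp_star - lp + lq_ratio
        accept <- log(uacc[i]) < log_alpha
      }
    }
    if (accept) {
      u <- u_star; lp <- lp_star; kw <- max(wd[1], 1e-300); cur <- sim_star
      cur_d <- wd[2]; cur_score <- sc_star
    }
    if (uniform && f > 1) {
      # monotone ratchet: the inflation floor tracks the best score seen so
      # far with ~30% headroom, so the chain can wander sideways but the
      # admissible region only tightens
      best_score <- min(best_score, cur_score)
      f <- if (cur_score <= 1) 1 else
        max(1 + 1.3 * (best_score - 1), f * f_decay)
    }
    if (!post_started) {
      if (i <= burn && config$adapt && is.null(proposal)) {
        # scale the random walk to the chain's own spread (2.4 sd / sqrt(p)),
        # burn-in only; the acceptance rate is then governed by the
        # threshold, which tune_mcmc_threshold() calibrates
        nw <- nw + 1L
        delta <- u - mw
        mw <- mw + delta / nw
        sw <- sw + delta * (u - mw)
        if (i %% 200L == 0L && nw > 50L) {
          sdv <- sqrt(sw / (nw - 1L))
          scale <- pmax(2.4 / sqrt(p) * sdv, 0.1 * scale0)
        }
      }
      if (i >= burn && f <= 1 && cur_score <= 1) post_started <- TRUE
      if (i >= anneal_deadline && (f > 1 || cur_score > 1)) {
        stop(sprintf("chain failed to reach the acceptance region during burn-in (residual threshold inflation %.3g); consider a larger threshold or longer burn-in", f))
      }
    } else {
      n_post_seen <- n_post_seen + 1L
      n_acc_post <- n_acc_post + as.integer(accept)
      if (n_post_seen %% thin == 0L) {
        kept <- kept + 1L
        theta_out[kept, ] <- from_inference_scale(model, u)
        d_out[kept] <- cur_d
        if (needs_pred) yt_out[[kept]] <- cur$ytilde
        if (needs_latent) v_out[[kept]] <- cur$v
      }
    }
  }
  if (kept == 0L) stop("no post-burn-in states stored; increase iterations")
  theta_out <- theta_out[seq_len(kept), , drop = FALSE]
  ytilde <- if (needs_pred) do.call(rbind, yt_out[seq_len(kept)]) else NULL
  v <- if (needs_latent) do.call(rbind, v_out[seq_len(kept)]) else NULL
  if (target$mode == "ABC_L") {
    ytilde <- t(vapply(seq_len(kept), function(j) {
      as.numeric(model$latent_cond_pred(theta_out[j, ], y_obs, v[j, ],
                                        seed = child_seed(seed, 3L, j)))
    }, FUN.VALUE = predict_template(model, theta_out[1, ], y_obs, v[1, ],
                                    seed = child_seed(seed, 3L, 1L))))
  }
  res <- weighted_samples(theta = theta_out, ytilde = ytilde, v = v,
                          weights = rep(1, kept), discrepancy = d_out[seq_len(kept)],
                          acceptance_rate = n_acc_post / max(n_post_seen, 1L),
                          mode = target$mode, seed = seed,
                          config = list(sampler = "mcmc",
                                        iterations = m, burn_in = burn,
                                        thin = thin,
                                        proposal_scale = scale))
  res$proposed_discrepancy <- prop_d
  res
}

mcmc_init <- function(model, prior, summary_fn, discrepancy, kernel, s_y,
                      seed, budget, init, needs_pred, ...) {
  if (!is.null(init)) {
    sim <- simulate_joint(model, init, seed = child_seed(seed, 10L, 0L),
                          predict = needs_pred, ...)
    s_z <- safe_summary(summary_fn, sim$y)
    wd <- kernel_weight(kernel, discrepancy, s_y, s_z)
    if (wd[1] > 0 && is.finite(prior$log_density(init))) {
      return(list(theta = init, sim = sim, kw = wd[1], d = wd[2],
                  score = kernel_score(kernel, discrepancy, s_y, s_z)))
    }
    stop("supplied initial state has zero kernel weight or zero prior density")
  }
  # independent prior draws; keep the best-scoring candidate.  With a
  # uniform kernel whose acceptance region has negligible prior-predictive
  # mass no draw may have positive weight; the chain then starts from the
  # best-scoring state and anneals the threshold down during burn-in.
  n1 <- min(budget, 2000L)
  theta <- prior$sample(n1, seed = child_seed(seed, 10L))
  best <- NULL
  for (i in seq_len(n1)) {
    sim <- simulate_joint(model, theta[i, ], seed = child_seed(seed, 10L, i),
                          predict = needs_pred, ...)
    s_z <- safe_summary(summary_fn, sim$y)
    wd <- kernel_weight(kernel, discrepancy, s_y, s_z)
    if (wd[1] > 0) {
      return(list(theta = theta[i, ], sim = sim, kw = wd[1], d = wd[2],
                  score = kernel_score(kernel, discrepancy, s_y, s_z)))
    }
    sc <- kernel_score(kernel, discrepancy, s_y, s_z)
    if (is.finite(sc) && (is.null(best) || sc < best$score)) {
      best <- list(theta = theta[i, ], sim = sim, kw = 0, d = wd[2],
                   score = sc)
    }
  }
  if (!is.null(best) && kernel_is_uniform(kernel)) return(best)
  stop(sprintf("no valid MCMC initial state found within %d prior draws; consider a larger threshold", as.integer(n1)))
}

#' ABC-F prediction step
#'
#' Given parameter draws from a standard ABC run, simulates one future-data
#' draw \eqn{\tilde y^{(i)} \sim \pi(\tilde y \mid \theta^{(i)}, y)} per
#' parameter draw via the model's conditional-predictive simulator; weights
#' are inherited.  Targets the ABC-F posterior predictive
#' \eqn{\int \pi(\tilde y \mid \theta, y)\,\hat\pi_h(\theta \mid s_y)\,
#' d\theta}.
#'
#' @param theta_samples an [weighted_samples()] with parameter draws.
#' @param model an [simulator_model()] with COND_PRED.
#' @param y_obs observed data conditioned on.
#' @param seed integer seed.
#' @export
abc_f_predict <- function(theta_samples, model, y_obs, seed) {
  require_capability(model, "COND_PRED",
                     "ABC-F prediction (conditional predictive law)")
  stopifnot(inherits(theta_samples, "abc_samples"), length(theta_samples) > 0)
  m <- nrow(theta_samples$theta)
  first <- as.numeric(model$cond_pred(theta_samples$theta[1, ], y_obs,
                                      seed = child_seed(seed, 4L, 1L)))
  yt <- matrix(NA_real_, m, length(first))
  yt[1, ] <- first
  if (m > 1) for (i in 2:m) {
    yt[i, ] <- as.numeric(model$cond_pred(theta_samples$theta[i, ], y_obs,
                                          seed = child_seed(seed, 4L, i)))
  }
  out <- theta_samples
  out$ytilde <- yt
  out$mode <- "ABC_F"
  out
}

#' Deferred prediction from stored latent states
#'
#' For runs that stored the latent variables / continuation state (deferred
#' ABC-P), simulates the future data
#' \eqn{\tilde y^{(i)} \sim \pi(\tilde y \mid z^{(i)}, v^{(i)}, \theta^{(i)})}
#' only for the requested indices (e.g. positive-weight, post-burn-in
#' records).  The resulting predictive law is distributionally identical to
#' having simulated \eqn{\tilde y} jointly with every proposal.
#'
#' @param run an [weighted_samples()] with stored latents `v`.
#' @param model an [simulator_model()] with LATENT_COND_PRED.
#' @param which integer indices of records to predict for (default: all).
#' @param seed integer seed.
#' @return `run` with `ytilde` filled for `which` (other rows `NA`), subset to
#'   `which`.
#' @export
deferred_prediction <- function(run, model, which = seq_len(length(run)), seed) {
  require_capability(model, "LATENT_COND_PRED", "deferred prediction")
  stopifnot(inherits(run, "abc_samples"))
  if (is.null(run$v)) stop("run does not store latent variables `v`")
  if (length(which) == 0L) {
    out <- run
    out$theta <- run$theta[0, , drop = FALSE]
    out$v <- run$v[0, , drop = FALSE]
    out$ytilde <- NULL
    out$weights <- numeric(0)
    return(out)
  }
  if (any(which < 1 | which > length(run))) stop("indices outside the run")
  yt <- t(vapply(which, function(i) {
    as.numeric(model$latent_cond_pred(run$theta[i, ], NULL, run$v[i, ],
                                      seed = child_seed(seed, 5L, i)))
  }, FUN.VALUE = predict_template(model, run$theta[which[1], ], NULL,
                                  run$v[which[1], ],
                                  seed = child_seed(seed, 5L, which[1]))))
  out <- run
  out$theta <- run$theta[which, , drop = FALSE]
  out$v <- run$v[which, , drop = FALSE]
  out$discrepancy <- run$discrepancy[which]
  ne <- normalize_and_ess(run$weights[which])
  out$weights <- ne$weights
  out$ess <- ne$ess
  out$ytilde <- yt
  out
}

#' Tune an acceptance threshold to a target MCMC acceptance rate
#'
#' Stage 1 calibrates the threshold as the target-rate quantile of
#' prior-predictive discrepancies ([calibrate_threshold()]).  A pilot chain is
#' then run; if its realized post-burn-in acceptance rate is off the target by
#' more than 50% relatively, the threshold is recalibrated once from the
#' chain's proposed-state discrepancies (which reflect the local, stationary
#' proposal distribution rather than the prior) and the pilot repeated.
#'
#' For a product kernel only `h_bar` is tuned; `h_tilde` stays fixed at its
#' scenario value, and the `h_bar` quantile is taken among draws already
#' passing the `h_tilde` factor so the joint rate matches the target.
#'
#' @inheritParams abc_mcmc
#' @param rate target acceptance rate.
#' @param n_pilot number of prior-predictive simulations for stage 1.
#' @param pilot_iterations pilot chain length.
#' @param max_retune maximum number of recalibration passes.
#' @return list with the tuned `kernel`, the stage-1 `h0`, and the realized
#'   pilot acceptance `rate`.
#' @export
tune_mcmc_threshold <- function(model, prior, summary_fn, discrepancy, kernel,
                                config, y_obs, seed, rate = 0.02,
                                n_pilot = 1e4, pilot_iterations = NULL,
                                max_retune = 4L, ...) {
  s_y <- as.numeric(summary_fn(y_obs))
  theta <- prior$sample(n_pilot, seed = child_seed(seed, 20L))
  d_bar <- numeric(n_pilot)
  pass_til <- rep(TRUE, n_pilot)
  for (i in seq_len(n_pilot)) {
    sim <- simulate_joint(model, theta[i, ], seed = child_seed(seed, 21L, i),
                          predict = FALSE, ...)
    s_z <- safe_summary(summary_fn, sim$y)
    if (is.null(s_z)) { d_bar[i] <- Inf; pass_til[i] <- FALSE; next }
    if (inherits(kernel, "abc_product_kernel")) {
      d_bar[i] <- compute_discrepancy(kernel$norm_bar,
                                      s_y[kernel$partition$bar],
                                      s_z[kernel$partition$bar])
      d_til <- compute_discrepancy(kernel$norm_tilde,
                                   s_y[kernel$partition$tilde],
                                   s_z[kernel$partition$tilde])
      pass_til[i] <- d_til <= kernel$h_tilde
    } else {
      d_bar[i] <- compute_discrepancy(discrepancy, s_y, s_z)
    }
  }
  h0 <- threshold_from_draws(d_bar, pass_til, rate)
  kernel <- set_threshold(kernel, h0)
  if (is.null(pilot_iterations)) {
    pilot_iterations <- min(config$iterations, 2e4)
  }
  pcfg <- mcmc_config(iterations = pilot_iterations,
                      burn_in = min(config$burn_in, floor(pilot_iterations / 2)),
                      proposal_scale = config$proposal_scale,
                      adapt = config$adapt, target_accept = rate,
                      init_budget = config$init_budget)
  pilot <- tryCatch(
    abc_mcmc(model, prior, summary_fn, discrepancy, kernel, pcfg,
             y_obs, seed = child_seed(seed, 22L),
             target = prediction_target("POSTERIOR"), ...),
    error = function(e) NULL)
  if (is.null(pilot)) {
    # pilot chain failed to reach the region within its short budget; keep
    # the stage-1 threshold and let the full-length run anneal into it
    return(list(kernel = kernel, h0 = h0, rate = NA_real_,
                proposal_scale = pcfg$proposal_scale))
  }
  realized <- pilot$acceptance_rate
  # retune from the pilot chain's proposed-state discrepancies until the
  # realized rate is within 50% of the target: the threshold and the
  # (spread-matched) proposal form a fixed point that a single pass does not
  # reach when the stage-1 prior-predictive threshold is far too loose.
  # The closest-to-target kernel seen is kept in case the iteration
  # overshoots (a too-tight threshold can leave the pilot chain nearly
  # stuck, which a later iteration cannot always recover from).
  rate_gap <- function(r) if (is.finite(r) && r > 0) abs(log(r / rate)) else Inf
  best <- list(kernel = kernel, rate = realized,
               scale = pilot$config$proposal_scale, gap = rate_gap(realized))
  iter <- 0L
  while (is.finite(realized) && abs(realized - rate) / rate > 0.5 &&
         iter < max_retune) {
    iter <- iter + 1L
    pd <- pilot$proposed_discrepancy
    ok <- is.finite(pd)
    h1 <- calibrate_threshold(pd[ok], rate)
    kernel <- set_threshold(kernel, h1)
    pilot2 <- tryCatch(
      abc_mcmc(model, prior, summary_fn, discrepancy, kernel, pcfg,
               y_obs, seed = child_seed(seed, 23L + iter),
               target = prediction_target("POSTERIOR"), ...),
      error = function(e) NULL)
    if (is.null(pilot2)) break
    pilot <- pilot2
    realized <- pilot$acceptance_rate
    if (rate_gap(realized) < best$gap) {
      best <- list(kernel = kernel, rate = realized,
                   scale = pilot$config$proposal_scale,
                   gap = rate_gap(realized))
    }
  }
  list(kernel = best$kernel, h0 = h0, rate = best$rate,
       proposal_scale = best$scale)
}

threshold_from_draws <- function(d_bar, pass_til, rate) {
  n <- length(d_bar)
  sub <- d_bar[pass_til & is.finite(d_bar)]
  if (length(sub) == 0L) {
    # rare prediction-block matches under the prior: fall back to the
    # unconditional quantile; the pilot-chain retuning step corrects it
    warning("no pilot draw passes the prediction-block threshold; ",
            "using the unconditional parameter-block quantile")
    sub <- d_bar[is.finite(d_bar)]
    if (length(sub) == 0L) stop("all pilot simulations failed")
    return(calibrate_threshold(sub, rate))
  }
  calibrate_threshold(sub, min(1, rate * n / length(sub)))
}

set_threshold <- function(kernel, h) {
  if (inherits(kernel, "abc_product_kernel")) {
    kernel$h_bar <- h
  } else {
    kernel$h <- h
  }
  kernel
}
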