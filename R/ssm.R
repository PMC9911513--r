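#' Gaussian linear state-space model parameters
#'
#' Latent AR(1) states \eqn{v_t \mid v_{t-1} \sim N(c + \phi v_{t-1},
#' \sigma^2)} with \eqn{v_0 = 0}, observed through independent Gaussian noise
#' \eqn{y_t \mid v_t \sim N(v_t, \omega^2)}.  Used to study summary-statistic
#' sufficiency for the latent-variable predictive approximation: the
#' one-step-ahead conditional predictive is
#' \eqn{\pi(y_{n+1} \mid v_n, c) = N(c + \phi v_n, \omega^2 + \sigma^2)}.
#'
#' @param c drift of the latent chain.
#' @param phi autoregression coefficient.
#' @param sigma2 latent innovation variance (> 0).
#' @param omega2 observation-noise variance (> 0).
#' @param n series length (> 1).
#' @export
ssm_params <- function(c = 1, phi = 0.5, sigma2 = 1, omega2 = 0.5, n = 20L) {
  stopifnot(sigma2 > 0, omega2 > 0, n > 1)
  structure(list(c = c, phi = phi, sigma2 = sigma2, omega2 = omega2,
                 n = as.integer(n)),
            class = "ssm_params")
}

# covariance of the latent states v_{1:N} (same kernel as the observed AR(1))
ssm_latent_cov <- function(N, phi, sigma2) ar1_covariance(N, phi, sigma2)

#' Simulate the state-space model
#'
#' @param params an [ssm_params()].
#' @param n_future number of future observations (continuing the latent
#'   chain).
#' @param seed integer seed.
#' @return list with latent states `v`, observations `y`, future observations
#'   `ytilde` and future latents `vtilde`.
#' @export
ssm_simulate <- function(params, n_future = 1L, seed) {
  stopifnot(inherits(params, "ssm_params"), n_future >= 0)
  set.seed(seed)
  N <- params$n + n_future
  eps <- stats::rnorm(N, sd = sqrt(params$sigma2))
  eta <- stats::rnorm(N, sd = sqrt(params$omega2))
  v <- as.numeric(stats::filter(params$c + eps, params$phi,
                                method = "recursive"))
  y <- v + eta
  idx <- seq_len(params$n)
  list(v = v[idx], y = y[idx],
       ytilde = if (n_future > 0) y[params$n + seq_len(n_future)] else numeric(0),
       vtilde = if (n_future > 0) v[params$n + seq_len(n_future)] else numeric(0))
}

#' Scalar summary statistics for the state-space model
#'
#' \eqn{s^{(1)}(y) = \mu^\top W^{-1} y} with \eqn{\mu_t = (1-\phi^t)/(1-\phi)}
#' is minimal parametric sufficient for the drift `c`;
#' \eqn{s^{(2)}(y) = \Sigma_{n:} W^{-1} y}, where \eqn{\Sigma} is the
#' latent-state covariance (\eqn{\mathrm{Cov}(v_s, v_t) = \sigma^2
#' \phi^{|t-s|}(1 - \phi^{2\min(s,t)})/(1-\phi^2)}) and
#' \eqn{W = \Sigma + \omega^2 I}, complements it: the pair is jointly
#' sufficient for \eqn{(v_n, c)} and a linear combination of the two is
#' minimal predictive sufficient for \eqn{y_{n+1}}.
#'
#' @param y observed series (length `params$n`).
#' @param params an [ssm_params()].
#' @return named vector `c(s1, s2)`.
#' @export
ssm_summaries <- function(y, params) {
  stopifnot(length(y) == params$n)
  n <- params$n
  mu <- ar1_mean_coeff(n, params$phi)
  Sigma <- ssm_latent_cov(n, params$phi, params$sigma2)
  W <- Sigma + params$omega2 * diag(n)
  Wi_y <- solve(W, y)
  c(s1 = drop(crossprod(mu, Wi_y)),
    s2 = drop(Sigma[n, ] %*% Wi_y))
}

# conditioning of (target block, c) on a linear functional L y of the data
# (L = identity for full-data conditioning); target: "c", "y_next", "vn_c"
ssm_condition <- function(y_or_s, params, L = NULL, target = "y_next") {
  n <- params$n
  phi <- params$phi
  mu <- ar1_mean_coeff(n + 1L, params$phi)
  Sigma <- ssm_latent_cov(n + 1L, params$phi, params$sigma2)
  W <- Sigma[seq_len(n), seq_len(n)] + params$omega2 * diag(n)
  if (is.null(L)) L <- diag(n)
  L <- matrix(L, ncol = n)
  a2 <- drop(L %*% mu[seq_len(n)])
  V22 <- L %*% W %*% t(L)
  obs <- as.numeric(y_or_s)
  if (target == "y_next") {
    # y_{n+1} = c + phi v_n + innovations + obs noise
    a1 <- mu[n + 1L]
    V11 <- phi^2 * Sigma[n, n] + params$sigma2 + params$omega2
    V12 <- matrix(phi * Sigma[n, seq_len(n)], 1) %*% t(L)
  } else if (target == "vn_c") {
    a1 <- mu[n]
    V11 <- Sigma[n, n]
    V12 <- matrix(Sigma[n, seq_len(n)], 1) %*% t(L)
  } else {  # "c"
    a1 <- 0
    V11 <- matrix(0)
    V12 <- rep(0, nrow(L))
  }
  gaussian_flat_prior_condition(a1 = a1, a2 = a2, V11 = V11, V12 = V12,
                                V22 = V22, obs = obs)
}

#' Exact posteriors for the state-space model via joint-normal conditioning
#'
#' Under the flat prior on `c`, conditions directly on the full data `y`
#' (the independent oracle for sufficiency tests).
#'
#' @param y observed series.
#' @param params an [ssm_params()].
#' @param target "c" for the drift posterior, "y_next" for the posterior
#'   predictive of \eqn{y_{n+1}}, or "vn_c" for the joint Gaussian posterior
#'   of \eqn{(v_n, c)}.
#' @return a [gaussian_density()] for scalar targets; for "vn_c" a list with
#'   `mean` (length 2) and `cov` (2x2) of \eqn{(v_n, c)}.
#' @export
ssm_exact_posterior <- function(y, params, target = c("c", "y_next", "vn_c")) {
  target <- match.arg(target)
  res <- ssm_condition(y, params, L = NULL, target = target)
  if (target == "c") {
    gaussian_density(res$c_mean, res$c_var)
  } else if (target == "y_next") {
    gaussian_density(res$mean, drop(res$cov))
  } else {
    list(mean = c(v_n = res$mean, c = res$c_mean),
         cov = rbind(c(drop(res$cov), res$cross),
                     c(res$cross, res$c_var)))
  }
}

#' Posterior given summary statistics only
#'
#' Same conditioning as [ssm_exact_posterior()] but on the scalar summaries
#' (or any linear functionals of the data) instead of the full series; used
#' to verify the sufficiency identities numerically.
#'
#' @inheritParams ssm_exact_posterior
#' @param which "s1", "s12" (the pair), or a numeric vector of coefficients
#'   `c(w1, w2)` defining the single statistic \eqn{w_1 s_1 + w_2 s_2}.
#' @export
ssm_summary_posterior <- function(y, params, target = c("c", "y_next", "vn_c"),
                                  which = "s1") {
  target <- match.arg(target)
  n <- params$n
  mu <- ar1_mean_coeff(n, params$phi)
  Sigma <- ssm_latent_cov(n, params$phi, params$sigma2)
  W <- Sigma + params$omega2 * diag(n)
  L1 <- drop(solve(W, mu))          # row vector of s1
  L2 <- drop(solve(W, Sigma[n, ]))  # row vector of s2
  L <- if (identical(which, "s1")) {
    matrix(L1, 1)
  } else if (identical(which, "s12")) {
    rbind(L1, L2)
  } else {
    matrix(which[1] * L1 + which[2] * L2, 1)
  }
  obs <- drop(L %*% y)
  res <- ssm_condition(obs, params, L = L, target = target)
  if (target == "c") {
    gaussian_density(res$c_mean, res$c_var)
  } else if (target == "y_next") {
    gaussian_density(res$mean, drop(res$cov))
  } else {
    list(mean = c(v_n = res$mean, c = res$c_mean),
         cov = rbind(c(drop(res$cov), res$cross),
                     c(res$cross, res$c_var)))
  }
}

#' Predictive-sufficient linear combination of the two summaries
#'
#' Finds weights \eqn{(w_1, w_2)} such that \eqn{w_1 s^{(1)} + w_2 s^{(2)}}
#' is minimal predictive sufficient for \eqn{y_{n+1}}: the exact predictive
#' mean is an exactly linear function of the two statistics in this Gaussian
#' model, so the weights are recovered by least squares across a handful of
#' simulated datasets.
#'
#' @param params an [ssm_params()].
#' @param n_data number of simulated datasets for the regression (>= 3).
#' @param seed integer seed.
#' @return named vector `c(w1, w2)` normalized to `w1 = 1` scale-free form
#'   when `w1 != 0`.
#' @export
ssm_predictive_coefficients <- function(params, n_data = 8L, seed = 1L) {
  S <- matrix(NA_real_, n_data, 2)
  mpred <- numeric(n_data)
  for (i in seq_len(n_data)) {
    sim <- ssm_simulate(params, n_future = 0L, seed = child_seed(seed, 30L, i))
    S[i, ] <- ssm_summaries(sim$y, params)
    mpred[i] <- ssm_exact_posterior(sim$y, params, "y_next")$mean
  }
  fit <- stats::lm.fit(x = S, y = mpred)
  w <- stats::setNames(fit$coefficients, c("w1", "w2"))
  resid <- max(abs(fit$residuals))
  if (resid > 1e-6 * max(abs(mpred))) {
    warning(sprintf("predictive mean is not exactly linear in (s1, s2); max residual %.3g", resid))
  }
  w
}

#' State-space simulator model for the ABC samplers
#'
#' JOINT_LATENT (the latent relevant for prediction is \eqn{v_n}) and
#' LATENT_COND_PRED (\eqn{y_{n+1} \mid v_n, c \sim N(c + \phi v_n,
#' \omega^2 + \sigma^2)}).
#'
#' @param phi,sigma2,omega2 fixed parameters.
#' @param n observed length.
#' @export
ssm_model <- function(phi = 0.5, sigma2 = 1, omega2 = 0.5, n = 20L) {
  force(phi); force(sigma2); force(omega2); force(n)
  simulate_joint <- function(theta, seed, predict = TRUE, ...) {
    pars <- ssm_params(c = theta[1], phi = phi, sigma2 = sigma2,
                       omega2 = omega2, n = n)
    sim <- ssm_simulate(pars, n_future = if (predict) 1L else 0L, seed = seed)
    list(y = sim$y, ytilde = sim$ytilde, v = sim$v[n])
  }
  latent_cond_pred <- function(theta, y, v, seed) {
    set.seed(seed)
    stats::rnorm(1, mean = theta[1] + phi * v[1],
                 sd = sqrt(omega2 + sigma2))
  }
  simulator_model("ssm", capabilities = c("JOINT_LATENT", "LATENT_COND_PRED"),
                  simulate_joint = simulate_joint,
                  latent_cond_pred = latent_cond_pred,
                  theta_names = "c", log_scale = FALSE,
                  extra = list(phi = phi, sigma2 = sigma2, omega2 = omega2,
                               n = n))
}
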