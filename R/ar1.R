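#' Gaussian AR(1) Markov chain parameters
#'
#' The worked Markov example: \eqn{y_t \mid y_{t-1} \sim N(c + \phi y_{t-1},
#' \sigma^2)} with \eqn{y_0 = 0}.  The drift `c` is the inference target;
#' \eqn{\phi} and \eqn{\sigma^2} are treated as known.  \eqn{|\phi| \ge 1} is
#' permitted (non-stationary regimes enter the acceptance-probability bound)
#' but inference experiments use \eqn{|\phi| < 1}.
#'
#' @param c drift.
#' @param phi autoregression coefficient.
#' @param sigma2 innovation variance (> 0).
#' @param n observed series length (> 1).
#' @export
ar1_params <- function(c = 1, phi = 0.5, sigma2 = 1, n = 100L) {
  stopifnot(sigma2 > 0, n > 1)
  structure(list(c = c, phi = phi, sigma2 = sigma2, n = as.integer(n)),
            class = "ar1_params")
}

#' Simulate an AR(1) path with a future segment
#'
#' Exact recursion from \eqn{y_0 = 0}; the observed block `y` (length `n`)
#' and the future block `ytilde` (length `n_future`, continuing from
#' \eqn{y_n}) are one joint draw.
#'
#' @param params an [ar1_params()].
#' @param n_future future segment length (>= 0).
#' @param seed integer seed.
#' @export
ar1_simulate <- function(params, n_future = 1L, seed) {
  stopifnot(inherits(params, "ar1_params"), n_future >= 0)
  set.seed(seed)
  N <- params$n + n_future
  eps <- stats::rnorm(N, sd = sqrt(params$sigma2))
  y <- as.numeric(stats::filter(params$c + eps, params$phi,
                                method = "recursive"))
  list(y = y[seq_len(params$n)],
       ytilde = if (n_future > 0) y[params$n + seq_len(n_future)] else numeric(0))
}

#' AR(1) summary statistics
#'
#' The three statistics whose interplay illustrates the dissociation between
#' parametric and predictive sufficiency:
#' \describe{
#'   \item{s1}{\eqn{\bar y_\phi = ((1-\phi)\sum_{i=1}^{n-1} y_i + y_n)/n} —
#'     minimal sufficient for the drift `c`.}
#'   \item{s2}{\eqn{(\bar y_\phi, y_n)} — sufficient for `c` and for
#'     \eqn{y_{n+p}}, any \eqn{p \ge 1}.}
#'   \item{s3}{\eqn{\mathring y_\phi = \bar y_\phi + \phi y_n} — predictive
#'     sufficient for \eqn{y_{n+1}} but a poor statistic for `c`.}
#' }
#'
#' @param y numeric series of length >= 2.
#' @param phi autoregression coefficient.
#' @param variant "s1", "s2" or "s3".
#' @export
ar1_summaries <- function(y, phi, variant = c("s1", "s2", "s3")) {
  variant <- match.arg(variant)
  n <- length(y)
  if (n < 2) stop("need at least two observations")
  ybar <- ((1 - phi) * sum(y[seq_len(n - 1)]) + y[n]) / n
  switch(variant,
         s1 = ybar,
         s2 = c(ybar, y[n]),
         s3 = ybar + phi * y[n])
}

# linear functionals on y_{1:n} realizing the summaries
ar1_summary_matrix <- function(n, phi, variant) {
  l1 <- c(rep((1 - phi) / n, n - 1), 1 / n)
  en <- c(rep(0, n - 1), 1)
  switch(variant,
         s1 = matrix(l1, 1),
         s2 = rbind(l1, en),
         s3 = matrix(l1 + phi * en, 1))
}

# mean coefficients mu_t = E[y_t | c = 1] and covariance of y_{1:N}
ar1_mean_coeff <- function(N, phi) {
  t <- seq_len(N)
  if (phi == 1) t else (1 - phi^t) / (1 - phi)
}

ar1_covariance <- function(N, phi, sigma2) {
  S <- matrix(0, N, N)
  for (s in seq_len(N)) for (t in seq_len(N)) {
    m <- min(s, t)
    S[s, t] <- if (phi^2 == 1) {
      sigma2 * phi^abs(t - s) * m
    } else {
      sigma2 * phi^abs(t - s) * (1 - phi^(2 * m)) / (1 - phi^2)
    }
  }
  S
}

#' Closed-form ABC posterior of the AR(1) drift
#'
#' Under the flat prior \eqn{\pi(c) \propto 1} and a Gaussian kernel between
#' the \eqn{\bar y_\phi} summaries, the ABC posterior of `c` is
#' \eqn{N(\bar y_\phi, \sigma^2/n + h^2)}; \code{h = 0} gives the exact
#' posterior.
#'
#' @param ybar_phi observed value of \eqn{\bar y_\phi}.
#' @param sigma2 innovation variance.
#' @param n series length.
#' @param h Gaussian-kernel bandwidth (>= 0).
#' @return a [gaussian_density()].
#' @export
ar1_abc_posterior_c <- function(ybar_phi, sigma2, n, h) {
  if (h < 0) stop("bandwidth h must be nonnegative")
  gaussian_density(ybar_phi, sigma2 / n + h^2)
}

#' Closed-form AR(1) posterior predictive oracles for \eqn{y_{n+1}}
#'
#' Gaussian-kernel targets under the flat prior on `c`:
#' \describe{
#'   \item{exact}{the exact posterior predictive
#'     \eqn{N(\mathring y_\phi, \sigma^2(1 + 1/n))}.}
#'   \item{abc_f}{the ABC-F target based on \eqn{\bar y_\phi}:
#'     \eqn{N(\mathring y_\phi, \sigma^2(1 + 1/n) + h^2)}; equals `exact` at
#'     \code{h = 0}.}
#'   \item{s1_only, s2, s3}{the ABC-P targets when acceptance is on
#'     \eqn{\bar y_\phi}, \eqn{(\bar y_\phi, y_n)} or \eqn{\mathring y_\phi}
#'     respectively, derived by exact joint-Gaussian conditioning of
#'     \eqn{(y_{n+1}, s(y))} under the flat prior (the kernel convolves each
#'     summary coordinate with \eqn{N(0, h^2)} noise).  At \code{h = 0} the
#'     `s2` and `s3` variants recover the exact predictive while `s1_only`
#'     has a strictly larger variance whenever \eqn{\phi \ne 0}.}
#' }
#'
#' @param y observed series.
#' @param phi,sigma2 fixed model parameters.
#' @param h kernel bandwidth (>= 0).
#' @param variant one of "exact", "abc_f", "s1_only", "s2", "s3".
#' @return a [gaussian_density()] for \eqn{y_{n+1}}.
#' @export
ar1_predictive_oracles <- function(y, phi, sigma2, h = 0,
                                   variant = c("exact", "abc_f", "s1_only",
                                               "s2", "s3")) {
  variant <- match.arg(variant)
  if (h < 0) stop("bandwidth h must be nonnegative")
  n <- length(y)
  ybar <- ar1_summaries(y, phi, "s1")
  yring <- ybar + phi * y[n]
  if (variant == "exact") {
    return(gaussian_density(yring, sigma2 * (1 + 1 / n)))
  }
  if (variant == "abc_f") {
    return(gaussian_density(yring, sigma2 * (1 + 1 / n) + h^2))
  }
  L <- ar1_summary_matrix(n, phi, switch(variant, s1_only = "s1",
                                         s2 = "s2", s3 = "s3"))
  res <- ar1_conditional(n, phi, sigma2, L, h, drop(L %*% y))
  gaussian_density(res$mean, drop(res$cov))
}

# joint-Gaussian conditioning of y_{n+1} on L y_{1:n} + kernel noise
ar1_conditional <- function(n, phi, sigma2, L, h, obs) {
  N <- n + 1L
  mu <- ar1_mean_coeff(N, phi)
  V <- ar1_covariance(N, phi, sigma2)
  a2 <- drop(L %*% mu[seq_len(n)])
  V22 <- L %*% V[seq_len(n), seq_len(n)] %*% t(L) + h^2 * diag(nrow(L))
  V12 <- matrix(V[N, seq_len(n)], 1) %*% t(L)
  gaussian_flat_prior_condition(a1 = mu[N], a2 = a2,
                                V11 = V[N, N], V12 = V12, V22 = V22,
                                obs = obs)
}

# ABC posterior of c via the same conditioning machinery (cross-check of the
# printed closed form): condition c on L y + kernel noise
ar1_posterior_c_conditional <- function(n, phi, sigma2, L, h, obs) {
  mu <- ar1_mean_coeff(n, phi)
  V <- ar1_covariance(n, phi, sigma2)
  a2 <- drop(L %*% mu)
  V22 <- L %*% V %*% t(L) + h^2 * diag(nrow(L))
  res <- gaussian_flat_prior_condition(a1 = 0, a2 = a2, V11 = matrix(0),
                                       V12 = rep(0, nrow(L)), V22 = V22,
                                       obs = obs)
  gaussian_density(res$c_mean, res$c_var)
}

#' Acceptance-probability bound for matching the last observation
#'
#' For the AR(1) chain with the single summary statistic \eqn{y_n}, the
#' maximum (over the drift `c`) probability of simulating data whose last
#' value matches the observed one within \eqn{\tilde h} satisfies
#' \deqn{\max_c P(|z_n - y_n| \le \tilde h \mid c) \;
#'   \begin{cases}
#'   \le \sqrt{2}\tilde h / \sqrt{\pi\sigma^2} \cdot
#'       \sqrt{\phi^2 - 1} / \sqrt{\phi^{2n} - 1}, & |\phi| > 1,\\
#'   \le \sqrt{2}\tilde h / (\sqrt{\pi\sigma^2}\sqrt{n}), & |\phi| = 1,\\
#'   \ge \sqrt{2}\tilde h / \sqrt{\pi\sigma^2} \cdot \sqrt{1 - \phi^2}\,
#'       e^{-\tilde h^2 / (2\sigma^2)}, & |\phi| < 1.
#'   \end{cases}}
#' In the non-stationary regimes the bound vanishes as \eqn{n \to \infty}
#' (matching the last value of a random walk becomes arbitrarily hard) while
#' in the stationary regime it is bounded below by a positive constant.
#'
#' @param phi autoregression coefficient.
#' @param sigma2 innovation variance.
#' @param n series length (>= 1).
#' @param h_tilde matching tolerance (> 0).
#' @return list with `value` and `direction` ("upper" or "lower").
#' @export
ar1_acceptance_bound <- function(phi, sigma2, n, h_tilde) {
  if (h_tilde <= 0) stop("h_tilde must be positive")
  stopifnot(n >= 1, sigma2 > 0)
  base <- sqrt(2) * h_tilde / sqrt(pi * sigma2)
  if (abs(phi) > 1) {
    list(value = base * sqrt(phi^2 - 1) / sqrt(phi^(2 * n) - 1),
         direction = "upper")
  } else if (abs(phi) == 1) {
    list(value = base / sqrt(n), direction = "upper")
  } else {
    list(value = base * sqrt(1 - phi^2) * exp(-h_tilde^2 / (2 * sigma2)),
         direction = "lower")
  }
}

#' AR(1) simulator model for the ABC samplers
#'
#' Packages the AR(1) example as an [simulator_model()] with JOINT and
#' COND_PRED capabilities.  The unknown parameter is the drift `c` alone;
#' \eqn{\phi} and \eqn{\sigma^2} are fixed.  Joint simulation draws the
#' observed block first so that runs sharing a seed stream share the
#' pseudo-data stream regardless of whether the future block is used.
#'
#' @param phi,sigma2 fixed parameters.
#' @param n observed length.
#' @param n_future future block length.
#' @export
ar1_model <- function(phi = 0.5, sigma2 = 1, n = 100L, n_future = 1L) {
  force(phi); force(sigma2); force(n); force(n_future)
  simulate_joint <- function(theta, seed, predict = TRUE, ...) {
    pars <- ar1_params(c = theta[1], phi = phi, sigma2 = sigma2, n = n)
    sim <- ar1_simulate(pars, n_future = if (predict) n_future else 0L,
                        seed = seed)
    list(y = sim$y, ytilde = sim$ytilde, v = sim$y[n])
  }
  cond_pred <- function(theta, y, seed) {
    set.seed(seed)
    out <- numeric(n_future)
    prev <- y[length(y)]
    for (t in seq_len(n_future)) {
      prev <- theta[1] + phi * prev + stats::rnorm(1, sd = sqrt(sigma2))
      out[t] <- prev
    }
    out
  }
  latent_cond_pred <- function(theta, y, v, seed) {
    # continuation depends on the path only through its last value
    cond_pred(theta, v[length(v)], seed)
  }
  simulator_model("ar1",
                  capabilities = c("JOINT", "JOINT_LATENT", "COND_PRED",
                                   "LATENT_COND_PRED"),
                  simulate_joint = simulate_joint, cond_pred = cond_pred,
                  latent_cond_pred = latent_cond_pred,
                  theta_names = "c", log_scale = FALSE,
                  extra = list(phi = phi, sigma2 = sigma2, n = n,
                               n_future = n_future))
}

#' Wide uniform surrogate for the flat drift prior
#'
#' The closed-form oracles use the improper flat prior exactly; the samplers
#' use this wide proper surrogate.
#'
#' @param half_width half-width of the box (default 50).
#' @export
ar1_flat_prior <- function(half_width = 50) {
  uniform_prior(lower = -half_width, upper = half_width, names = "c")
}
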