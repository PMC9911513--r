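#' M/G/1 queue parameters
#'
#' Single-server queue with Poisson arrivals (interarrival times
#' \eqn{w_i \sim \mathrm{Exp}(\theta_3)}) and uniform service times
#' \eqn{u_i \sim U([\theta_1, \theta_2])}.  Only the interdeparture times are
#' observed; the inference target is the waiting times of future customers.
#'
#' @param theta1 minimum service time (>= 0).
#' @param theta2 maximum service time (>= theta1).
#' @param theta3 arrival rate (> 0).
#' @export
mg1_params <- function(theta1, theta2, theta3) {
  stopifnot(theta1 >= 0, theta2 >= theta1, theta3 > 0)
  structure(list(theta1 = theta1, theta2 = theta2, theta3 = theta3),
            class = "mg1_params")
}

#' Simulate the M/G/1 queue
#'
#' Runs the interdeparture recursion \eqn{y_i = u_i + \max\{0, v_i -
#' x_{i-1}\}} with \eqn{v_0 = x_0 = 0}, where \eqn{v_i} are arrival and
#' \eqn{x_i} departure times, for customers \eqn{1, \ldots, n + \tilde n}.
#' Waiting times \eqn{\omega_i = x_i - v_i} include the service time, so
#' \eqn{\omega_i \ge u_i \ge \theta_1} on every trajectory.
#'
#' @param params an [mg1_params()].
#' @param n number of observed customers.
#' @param ntilde number of future customers.
#' @param seed integer seed.
#' @param u,w optional injected service / interarrival times (length
#'   `n + ntilde`) for deterministic checks.
#' @return list with `y`, `v`, `x`, `u`, `omega` (all length `n + ntilde`)
#'   and `n`.
#' @export
mg1_simulate <- function(params, n, ntilde = 0L, seed = NULL, u = NULL,
                         w = NULL) {
  stopifnot(inherits(params, "mg1_params"), n >= 0, ntilde >= 0)
  N <- n + ntilde
  if (is.null(u) || is.null(w)) {
    set.seed(seed)
    if (is.null(u)) u <- stats::runif(N, params$theta1, params$theta2)
    if (is.null(w)) w <- stats::rexp(N, rate = params$theta3)
  }
  stopifnot(length(u) == N, length(w) == N)
  out <- mg1_recurse_cpp(u, w, 0, 0)
  out$n <- n
  out
}

#' Continue the queue from a stored state
#'
#' Simulates the waiting times of the next `ntilde` customers given the
#' sufficient continuation state: the last departure time \eqn{x_n} and last
#' arrival time \eqn{v_n}.  This is the latent-conditional prediction step of
#' the queue (\eqn{\pi(\tilde\omega \mid y, v, \theta) = \pi(\tilde\omega
#' \mid x_n, v_n, \theta)}).
#'
#' @param params an [mg1_params()].
#' @param x_n last departure time.
#' @param v_n last arrival time (must satisfy `x_n >= v_n`).
#' @param ntilde number of future customers (>= 1).
#' @param seed integer seed.
#' @param u,w optional injected service / interarrival times.
#' @return list with the future `y`, `v`, `x`, `u`, `omega`.
#' @export
mg1_conditional_predict <- function(params, x_n, v_n, ntilde, seed = NULL,
                                    u = NULL, w = NULL) {
  stopifnot(ntilde >= 1)
  if (x_n < v_n) stop("inconsistent queue state: x_n < v_n")
  if (is.null(u) || is.null(w)) {
    set.seed(seed)
    if (is.null(u)) u <- stats::runif(ntilde, params$theta1, params$theta2)
    if (is.null(w)) w <- stats::rexp(ntilde, rate = params$theta3)
  }
  mg1_recurse_cpp(u, w, x_n, v_n)
}

#' Summary statistics for the queue
#'
#' The 5-dimensional baseline `s0` consists of the empirical 0.25, 0.5 and
#' 0.75 quantiles of the interdeparture times plus their range encoded as the
#' pair (min, max) — the pair rather than the scalar max-min keeps the
#' statistic 5-dimensional.  `s1` appends three prediction-informative
#' indices \eqn{\max\{i \ge 1 : y_i \ge \hat q_{\tilde\alpha}(y_{obs})\}} for
#' \eqn{\tilde\alpha \in \{0.7, 0.8, 0.9\}} (convention \eqn{\max\emptyset =
#' 1}): the position of the most recent large interdeparture time signals a
#' recently-empty queue.  The reference thresholds are computed once from the
#' observed data, not from each simulated set.  Quantiles use type-7 linear
#' interpolation.
#'
#' @param y interdeparture times.
#' @param variant "s0" or "s1".
#' @param y_obs_ref observed data from which the `s1` thresholds are taken
#'   (required for "s1").
#' @export
mg1_summaries <- function(y, variant = c("s0", "s1"), y_obs_ref = NULL) {
  variant <- match.arg(variant)
  if (length(y) == 0L) stop("empty interdeparture series")
  s0 <- c(stats::quantile(y, c(0.25, 0.5, 0.75), names = FALSE, type = 7),
          min(y), max(y))
  names(s0) <- c("q25", "q50", "q75", "min", "max")
  if (variant == "s0") return(s0)
  if (is.null(y_obs_ref)) stop("s1 requires the observed reference data")
  thr <- stats::quantile(y_obs_ref, c(0.7, 0.8, 0.9), names = FALSE, type = 7)
  idx <- vapply(thr, function(q) {
    hit <- which(y >= q)
    if (length(hit) == 0L) 1L else max(hit)
  }, integer(1))
  c(s0, stats::setNames(as.numeric(idx), c("idx70", "idx80", "idx90")))
}

#' Prior for the queue parameters
#'
#' \eqn{(\theta_1, \theta_2 - \theta_1, \theta_3) \sim U([0,10]^2 \times
#' [0, 1/3])}, truncated to the data-dependent constraint \eqn{\theta_1 \le
#' \min_i y_i} (implicit in the exact likelihood but not in the ABC
#' acceptance).  The sampler rejects draws violating the truncation.
#'
#' @param y_obs observed interdeparture times (all > 0).
#' @export
mg1_prior <- function(y_obs) {
  ymin <- min(y_obs)
  stopifnot(ymin > 0)
  sample <- function(n, seed) {
    set.seed(seed)
    out <- matrix(NA_real_, n, 3)
    filled <- 0L
    while (filled < n) {
      k <- max(2L * (n - filled), 64L)
      t1 <- stats::runif(k, 0, 10)
      gap <- stats::runif(k, 0, 10)
      t3 <- stats::runif(k, 0, 1 / 3)
      ok <- which(t1 <= ymin)
      if (length(ok) > 0L) {
        take <- ok[seq_len(min(length(ok), n - filled))]
        rows <- filled + seq_along(take)
        out[rows, ] <- cbind(t1[take], t1[take] + gap[take], t3[take])
        filled <- filled + length(take)
      }
    }
    colnames(out) <- c("theta1", "theta2", "theta3")
    out
  }
  log_density <- function(theta) {
    t1 <- theta[1]; t2 <- theta[2]; t3 <- theta[3]
    ok <- t1 >= 0 && t1 <= 10 && (t2 - t1) >= 0 && (t2 - t1) <= 10 &&
      t3 >= 0 && t3 <= 1 / 3 && t1 <= ymin
    if (ok) 0 else -Inf  # constant on the truncated box (unnormalized)
  }
  prior_spec(sample, log_density, p = 3L,
             names = c("theta1", "theta2", "theta3"))
}

#' M/G/1 simulator model for the ABC samplers
#'
#' JOINT simulation of \eqn{(\tilde\omega, y) \mid \theta} (future waiting
#' times alongside observed interdeparture times), JOINT_LATENT with the
#' continuation state \eqn{(x_n, v_n)} as the stored latent, and
#' LATENT_COND_PRED via [mg1_conditional_predict()].  In the latent
#' prediction step the departure clock \eqn{x_n} is taken from the data
#' argument when supplied (ABC-L conditions on the observed series) and from
#' the stored state otherwise (deferred ABC-P continues the simulated
#' series).  ABC-F is not available: simulating \eqn{\tilde\omega \mid y,
#' \theta} directly is blocked by the latent arrival times.
#'
#' @param n observed number of customers.
#' @param ntilde number of future customers.
#' @export
mg1_model <- function(n = 100L, ntilde = 10L) {
  force(n); force(ntilde)
  simulate_joint <- function(theta, seed, predict = TRUE, ...) {
    pars <- mg1_params(theta[1], theta[2], theta[3])
    # the full-length randomness is always drawn so the observed block (and
    # hence acceptance) is identical whether or not the future block is used
    sim <- mg1_simulate(pars, n = n, ntilde = ntilde, seed = seed)
    list(y = sim$y[seq_len(n)],
         ytilde = if (predict) sim$omega[n + seq_len(ntilde)] else NULL,
         v = c(x_n = sim$x[n], v_n = sim$v[n]))
  }
  latent_cond_pred <- function(theta, y, v, seed) {
    pars <- mg1_params(theta[1], theta[2], theta[3])
    x_n <- if (!is.null(y)) sum(y) else v[1]
    v_n <- v[length(v)]
    # a simulated arrival clock can exceed the *observed* departure clock it
    # is paired with; clamp to keep the continuation state consistent
    mg1_conditional_predict(pars, x_n, min(v_n, x_n), ntilde = ntilde,
                            seed = seed)$omega
  }
  simulator_model("mg1",
                  capabilities = c("JOINT", "JOINT_LATENT", "LATENT_COND_PRED"),
                  simulate_joint = simulate_joint,
                  latent_cond_pred = latent_cond_pred,
                  theta_names = c("theta1", "theta2", "theta3"),
                  log_scale = rep(FALSE, 3),
                  extra = list(n = n, ntilde = ntilde))
}
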