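#' Simulator model capability contract
#'
#' A simulator model declares which conditional laws of the model it can
#' sample from, mirroring the feasibility assumptions of the three predictive
#' ABC approximations:
#' \describe{
#'   \item{JOINT}{sample \eqn{(y, \tilde{y}) \mid \theta} jointly — required
#'     by ABC-P and by standard ABC parameter inference.}
#'   \item{JOINT_LATENT}{sample \eqn{(y, v, \tilde{y}) \mid \theta} where `v`
#'     are finite-dimensional latent variables — required by ABC-L and by
#'     deferred prediction.}
#'   \item{COND_PRED}{sample \eqn{\tilde{y} \mid y, \theta} — required by
#'     ABC-F.}
#'   \item{LATENT_COND_PRED}{sample \eqn{\tilde{y} \mid y, v, \theta} —
#'     required by ABC-L's prediction step and by deferred prediction.}
#' }
#'
#' The `simulate_joint` procedure takes `(theta, seed, ...)` and must return a
#' list with elements `y` (observed-size data), `ytilde` (future data) and
#' optionally `v` (latent variables) and `state` (sufficient continuation
#' state).  When JOINT_LATENT is declared, JOINT follows by simply ignoring
#' `v`.  `cond_pred(theta, y, seed)` returns a `ytilde` draw;
#' `latent_cond_pred(theta, y, v, seed)` likewise given the latents.
#'
#' @param name model name.
#' @param capabilities character subset of
#'   \code{c("JOINT", "JOINT_LATENT", "COND_PRED", "LATENT_COND_PRED")}.
#' @param simulate_joint,cond_pred,latent_cond_pred simulation procedures
#'   (functions) for the declared capabilities.
#' @param theta_names parameter coordinate names.
#' @param log_scale logical per-coordinate flag: inference on the log scale
#'   (coordinate must then be strictly positive on the natural scale).
#' @param extra list of model-specific fields carried along.
#' @return an object of class \code{"abc_model"}.
#' @export
simulator_model <- function(name, capabilities, simulate_joint = NULL,
                            cond_pred = NULL, latent_cond_pred = NULL,
                            theta_names = NULL, log_scale = NULL,
                            extra = list()) {
  caps <- match.arg(capabilities,
                    c("JOINT", "JOINT_LATENT", "COND_PRED", "LATENT_COND_PRED"),
                    several.ok = TRUE)
  if ("JOINT_LATENT" %in% caps && !("JOINT" %in% caps)) {
    caps <- c(caps, "JOINT")  # marginalizing v yields a JOINT draw
  }
  need <- c(JOINT = "simulate_joint", JOINT_LATENT = "simulate_joint",
            COND_PRED = "cond_pred", LATENT_COND_PRED = "latent_cond_pred")
  procs <- list(simulate_joint = simulate_joint, cond_pred = cond_pred,
                latent_cond_pred = latent_cond_pred)
  for (cap in caps) {
    if (is.null(procs[[need[[cap]]]])) {
      stop("capability ", cap, " declared but procedure `", need[[cap]],
           "` is missing")
    }
  }
  if (is.null(log_scale) && !is.null(theta_names)) {
    log_scale <- rep(FALSE, length(theta_names))
  }
  structure(list(name = name, capabilities = caps,
                 simulate_joint = simulate_joint, cond_pred = cond_pred,
                 latent_cond_pred = latent_cond_pred,
                 theta_names = theta_names, log_scale = log_scale,
                 extra = extra),
            class = "abc_model")
}

#' @export
print.abc_model <- function(x, ...) {
  cat(sprintf("Simulator model \"%s\"\n  capabilities: %s\n  parameters: %s\n",
              x$name, paste(x$capabilities, collapse = ", "),
              if (is.null(x$theta_names)) "(unnamed)"
              else paste(x$theta_names, collapse = ", ")))
  invisible(x)
}

has_capability <- function(model, cap) cap %in% model$capabilities

require_capability <- function(model, cap, what) {
  if (!has_capability(model, cap)) {
    stop(sprintf("%s requires the %s capability, which model \"%s\" does not declare",
                 what, cap, model$name))
  }
}

#' Draw from the model jointly
#'
#' Wrapper around the model's joint simulator; returns a list with `y`,
#' `ytilde` and, for latent-variable models, `v` and/or `state`.
#'
#' @param model an [simulator_model()].
#' @param theta parameter vector (natural scale).
#' @param seed integer seed.
#' @param ... passed to the model's procedure.
#' @export
simulate_joint <- function(model, theta, seed, ...) {
  require_capability(model, "JOINT", "joint simulation")
  model$simulate_joint(theta, seed = seed, ...)
}

#' Prior distribution specification
#'
#' @param sample function `(n, seed)` returning an `n x p` matrix of draws on
#'   the natural scale, all satisfying the support constraints.
#' @param log_density function `(theta)` returning the log prior density
#'   (possibly unnormalized) or `-Inf` outside the support.
#' @param p parameter dimension.
#' @param names parameter coordinate names.
#' @return an object of class \code{"abc_prior"}.
#' @export
prior_spec <- function(sample, log_density, p, names = NULL) {
  stopifnot(is.function(sample), is.function(log_density))
  structure(list(sample = sample, log_density = log_density, p = as.integer(p),
                 names = names),
            class = "abc_prior")
}

#' @export
print.abc_prior <- function(x, ...) {
  cat(sprintf("ABC prior over %d parameter(s)%s\n", x$p,
              if (is.null(x$names)) "" else
                paste0(": ", paste(x$names, collapse = ", "))))
  invisible(x)
}

#' Uniform box prior
#'
#' Independent uniform coordinates on `[lower, upper]`, optionally on the log
#' scale (draws are exponentiated back to the natural scale, as for the
#' predator-prey rate parameters).
#'
#' @param lower,upper numeric bounds per coordinate.
#' @param log_scale logical; if TRUE the box lives on the log scale.
#' @param names coordinate names.
#' @export
uniform_prior <- function(lower, upper, log_scale = FALSE, names = NULL) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  p <- length(lower)
  ld_const <- -sum(log(upper - lower))
  sample <- function(n, seed) {
    set.seed(seed)
    u <- matrix(stats::runif(n * p), nrow = n)
    th <- sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
    if (log_scale) th <- exp(th)
    colnames(th) <- names
    th
  }
  log_density <- function(theta) {
    th <- if (log_scale) {
      if (any(theta <= 0)) return(-Inf)
      log(theta)
    } else theta
    if (all(th >= lower & th <= upper)) ld_const else -Inf
  }
  prior_spec(sample, log_density, p = p, names = names)
}
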