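#' Acceptance kernel specification
#'
#' An ABC kernel maps a nonnegative discrepancy value to an acceptance weight
#' in \code{[0, 1]}.  Two kernels are supported: the uniform (indicator)
#' kernel \eqn{K_h(r) = 1\{r \le h\}} and the Gaussian kernel
#' \eqn{K_h(r) = \exp(-r^2 / (2 h^2))}.  The bandwidth \code{h} controls the
#' accuracy/efficiency trade-off of the ABC approximation: \code{h = 0}
#' accepts only exact summary matches while \code{h = Inf} accepts everything
#' (the prior, or prior-predictive, limit).
#'
#' @param kind "uniform" or "gaussian".
#' @param h nonnegative bandwidth (threshold); may be \code{Inf}.
#' @return an object of class \code{"abc_kernel"}.
#' @export
kernel_spec <- function(kind = c("uniform", "gaussian"), h) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(h), length(h) == 1L, !is.na(h))
  if (h < 0) stop("kernel bandwidth `h` must be nonnegative")
  structure(list(kind = kind, h = as.numeric(h)), class = "abc_kernel")
}

#' @export
print.abc_kernel <- function(x, ...) {
  cat(sprintf("ABC kernel: %s, h = %g\n", x$kind, x$h))
  invisible(x)
}

#' Evaluate an acceptance kernel at a discrepancy value
#'
#' @param kernel an [kernel_spec()] object.
#' @param r nonnegative discrepancy value(s).
#' @return weight(s) in \code{[0, 1]}; vectorized over `r`.
#' @export
evaluate_kernel <- function(kernel, r) {
  stopifnot(inherits(kernel, "abc_kernel"), is.numeric(r))
  if (any(r < 0, na.rm = TRUE)) stop("discrepancy `r` must be nonnegative")
  h <- kernel$h
  if (is.infinite(h)) return(rep(1, length(r)))
  if (kernel$kind == "uniform") {
    as.numeric(r <= h)
  } else {
    if (h == 0) as.numeric(r == 0) else exp(-r^2 / (2 * h^2))
  }
}

#' Discrepancy (norm) specification for summary-statistic comparison
#'
#' Defines the nonnegative distance between an observed and a simulated
#' summary vector.  Supported kinds:
#' \describe{
#'   \item{"weighted"}{\eqn{\sum_i w_i (a_i - b_i)^2} with nonnegative
#'     per-coordinate weights, e.g. reciprocals of squared median absolute
#'     deviations of pilot summaries.}
#'   \item{"mahalanobis"}{\eqn{r^\top C^{-1} r} with \eqn{r = a - b} and a
#'     positive-definite matrix \eqn{C}, typically the empirical covariance
#'     of pilot summaries.  Note this quadratic form lives on the *squared*
#'     scale; thresholds for it are therefore also on the squared scale.}
#'   \item{"linf"}{\eqn{\max_i |a_i - b_i|}.}
#' }
#'
#' @param kind one of "weighted", "mahalanobis", "linf".
#' @param weights numeric vector of nonnegative weights ("weighted") or a
#'   positive-definite matrix ("mahalanobis"); ignored for "linf".
#' @param provenance optional character note on how the weights were obtained.
#' @return an object of class \code{"abc_discrepancy"}.
#' @export
discrepancy_spec <- function(kind = c("weighted", "mahalanobis", "linf"),
                             weights = NULL, provenance = NULL) {
  kind <- match.arg(kind)
  prec <- NULL
  if (kind == "weighted") {
    stopifnot(is.numeric(weights), length(weights) >= 1L)
    if (any(weights < 0)) stop("weights must be nonnegative")
  } else if (kind == "mahalanobis") {
    stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
    ev <- eigen(weights, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("covariance matrix must be positive-definite")
    prec <- solve(weights)
  }
  structure(list(kind = kind, weights = weights, precision = prec,
                 provenance = provenance),
            class = "abc_discrepancy")
}

#' Compute the discrepancy between two summary vectors
#'
#' Symmetric in its arguments and zero iff the summaries are equal (for
#' positive weights / positive-definite matrix).
#'
#' @param spec an [discrepancy_spec()] object.
#' @param s_a,s_b numeric summary vectors of equal length.
#' @return a single nonnegative number.
#' @export
compute_discrepancy <- function(spec, s_a, s_b) {
  stopifnot(inherits(spec, "abc_discrepancy"))
  if (length(s_a) != length(s_b)) {
    stop("summary vectors have different lengths (", length(s_a), " vs ",
         length(s_b), ")")
  }
  r <- as.numeric(s_a) - as.numeric(s_b)
  switch(spec$kind,
         linf = max(abs(r)),
         weighted = {
           if (length(spec$weights) != length(r)) {
             stop("weight vector length does not match summary dimension")
           }
           sum(spec$weights * r^2)
         },
         mahalanobis = {
           if (nrow(spec$precision) != length(r)) {
             stop("precision matrix dimension does not match summary dimension")
           }
           drop(crossprod(r, spec$precision %*% r))
         })
}

#' Two-block product-kernel acceptance
#'
#' Acceptance rule for a partitioned summary statistic
#' \eqn{s(y) = (\bar{s}(y), \tilde{s}(y))} where the first block is deemed
#' informative for the parameters and the second for prediction.  Accepts iff
#' \eqn{\|\bar{s}_y - \bar{s}_z\| \le \bar{h}} *and*
#' \eqn{\|\tilde{s}_y - \tilde{s}_z\|' \le \tilde{h}}, with per-block norms
#' and thresholds.  Both comparisons use \code{<=} so that boundary ties are
#' accepted.  With an empty prediction block the rule reduces to the standard
#' single-kernel uniform acceptance.
#'
#' @param s_y,s_z full summary vectors (observed and simulated).
#' @param partition list with integer index vectors \code{bar} and
#'   \code{tilde} partitioning \code{seq_along(s_y)}.
#' @param norm_bar,norm_tilde [discrepancy_spec()] objects for the two blocks.
#' @param h_bar,h_tilde nonnegative per-block thresholds.
#' @return 1 (accept) or 0 (reject).
#' @export
product_kernel_accept <- function(s_y, s_z, partition, norm_bar, norm_tilde,
                                  h_bar, h_tilde) {
  if (is.null(partition) || is.null(partition$bar)) {
    stop("a summary partition with a `bar` block is required")
  }
  if (length(s_y) != length(s_z)) stop("summary vectors have different lengths")
  idx <- sort(c(partition$bar, partition$tilde))
  if (!identical(idx, seq_along(s_y))) {
    stop("partition blocks must cover the summary coordinates exactly once")
  }
  d_bar <- compute_discrepancy(norm_bar, s_y[partition$bar], s_z[partition$bar])
  ok <- d_bar <= h_bar
  if (ok && length(partition$tilde) > 0L) {
    d_til <- compute_discrepancy(norm_tilde, s_y[partition$tilde],
                                 s_z[partition$tilde])
    ok <- d_til <= h_tilde
  }
  as.numeric(ok)
}

#' Estimate discrepancy weights from pilot simulations
#'
#' Runs the model's joint simulator \code{n_pilot} times at a reference
#' parameter value and estimates either the empirical covariance matrix of
#' the summaries (\code{method = "cov"}; used in a Mahalanobis-type quadratic
#' form) or per-coordinate weights \eqn{1 / \mathrm{MAD}_i^2}
#' (\code{method = "mad"}).  The covariance estimate is ridge-regularized by
#' \code{eps * diag(C)} before use, because pilot covariances of correlated
#' summaries can be near-singular.
#'
#' @param model an [simulator_model()] with the JOINT capability.
#' @param theta_ref reference parameter value (natural scale).
#' @param summary_fn function mapping a simulated data set to a summary vector.
#' @param n_pilot number of pilot simulations (>= 2).
#' @param method "cov" or "mad".
#' @param seed integer seed.
#' @param eps ridge regularization factor for "cov".
#' @return an [discrepancy_spec()] ("mahalanobis" for cov, "weighted" for mad).
#' @export
estimate_summary_weights <- function(model, theta_ref, summary_fn,
                                     n_pilot = 1000L,
                                     method = c("cov", "mad"),
                                     seed = 1L, eps = 1e-8) {
  method <- match.arg(method)
  stopifnot(n_pilot >= 2)
  sims <- lapply(seq_len(n_pilot), function(i) {
    sim <- simulate_joint(model, theta_ref, seed = child_seed(seed, 7L, i))
    as.numeric(summary_fn(sim$y))
  })
  S <- do.call(rbind, sims)
  nm <- colnames(S)
  if (is.null(nm)) nm <- paste0("s", seq_len(ncol(S)))
  spread <- apply(S, 2, stats::sd)
  if (any(spread == 0)) {
    bad <- which(spread == 0)
    stop("summary coordinate(s) with zero pilot variability: ",
         paste(paste0(bad, " (", nm[bad], ")"), collapse = ", "))
  }
  if (method == "mad") {
    m <- apply(S, 2, stats::mad, constant = 1)  # raw median absolute deviation
    if (any(m == 0)) {
      bad <- which(m == 0)
      stop("summary coordinate(s) with zero pilot MAD: ",
           paste(paste0(bad, " (", nm[bad], ")"), collapse = ", "))
    }
    discrepancy_spec("weighted", weights = 1 / m^2,
                     provenance = sprintf("1/MAD^2 of %d pilot summaries", n_pilot))
  } else {
    C <- stats::cov(S)
    C <- C + eps * diag(diag(C), nrow = nrow(C))
    discrepancy_spec("mahalanobis", weights = C,
                     provenance = sprintf("covariance of %d pilot summaries", n_pilot))
  }
}

#' Calibrate an acceptance threshold from discrepancy draws
#'
#' Returns the empirical quantile of the supplied discrepancy draws such that
#' the fraction of draws at or below the returned value matches the target
#' acceptance rate (to within one draw).  Used to translate a target
#' acceptance rate (e.g. the 2% ABC-MCMC rate of the queue and predator-prey
#' experiments) into a threshold \code{h}.
#'
#' @param draws nonempty numeric vector of discrepancy values.
#' @param rate target acceptance rate in \code{(0, 1]}.
#' @return threshold \code{h}.
#' @export
calibrate_threshold <- function(draws, rate) {
  if (length(draws) == 0L) stop("no discrepancy draws supplied")
  stopifnot(is.numeric(rate), length(rate) == 1L, rate > 0, rate <= 1)
  sorted <- sort(draws)
  k <- max(1L, ceiling(rate * length(sorted)))
  sorted[k]
}

#' Normalize importance weights and compute the effective sample size
#'
#' @param weights nonnegative, not-all-zero weights.
#' @return list with `weights` (summing to 1) and `ess`
#'   (\eqn{1 / \sum_i \omega_i^2}; equals `m` for uniform weights).
#' @export
normalize_and_ess <- function(weights) {
  stopifnot(is.numeric(weights), length(weights) >= 1L)
  if (any(weights < 0)) stop("weights must be nonnegative")
  tot <- sum(weights)
  if (tot == 0) {
    stop("all importance weights are zero (no draws accepted)")
  }
  w <- weights / tot
  ess <- 1 / sum(w^2)
  if (ess < 0.01 * length(w)) {
    warning(sprintf("effective sample size %.1f is below 1%% of m = %d",
                    ess, length(w)))
  }
  list(weights = w, ess = ess)
}

# Deterministic child-seed derivation: one root seed per experiment, Lehmer-style
# mixing per (stream, index) so that independent components get reproducible,
# non-overlapping seeds below 2^31.
child_seed <- function(seed, stream, i = 0L) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m + 1)
  s <- (s * 48271) %% m
  s <- ((s + as.numeric(stream) * 69621 + as.numeric(i)) * 16807) %% m
  s <- (s * 48271) %% m
  as.integer(s)
}
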