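#' Weighted ABC sample set
#'
#' Container for the output of the ABC samplers: parameter draws, optional
#' predictive draws and latent variables, normalized nonnegative weights,
#' realized discrepancy values and acceptance diagnostics.
#'
#' @param theta matrix of parameter draws (one row per draw, natural scale).
#' @param ytilde optional matrix of predictive draws (rows aligned with theta).
#' @param v optional matrix of latent-variable draws.
#' @param state optional list of continuation states for deferred prediction.
#' @param weights nonnegative weights; normalized internally.
#' @param discrepancy realized discrepancy per draw.
#' @param acceptance_rate fraction of proposals accepted / positive-weight draws.
#' @param mode one of "POSTERIOR", "ABC_F", "ABC_P", "ABC_L".
#' @param seed root seed used.
#' @param config list echoing resolved sampler settings.
#' @return object of class \code{"abc_samples"}.
#' @export
weighted_samples <- function(theta, ytilde = NULL, v = NULL, state = NULL,
                             weights = NULL, discrepancy = NULL,
                             acceptance_rate = NA_real_, mode = "POSTERIOR",
                             seed = NA_integer_, config = list()) {
  theta <- as.matrix(theta)
  m <- nrow(theta)
  if (is.null(weights)) weights <- rep(1, m)
  stopifnot(length(weights) == m)
  if (!is.null(ytilde)) {
    ytilde <- as.matrix(ytilde)
    stopifnot(nrow(ytilde) == m)
  }
  if (!is.null(v)) {
    v <- as.matrix(v)
    stopifnot(nrow(v) == m)
  }
  ne <- normalize_and_ess(weights)
  structure(list(theta = theta, ytilde = ytilde, v = v, state = state,
                 weights = ne$weights, ess = ne$ess,
                 discrepancy = discrepancy,
                 acceptance_rate = acceptance_rate, mode = mode,
                 seed = seed, config = config),
            class = "abc_samples")
}

#' @export
print.abc_samples <- function(x, ...) {
  cat(sprintf("ABC sample set (%s): %d draws, ESS %.1f, acceptance rate %s\n",
              x$mode, nrow(x$theta), x$ess,
              if (is.na(x$acceptance_rate)) "NA"
              else sprintf("%.3f", x$acceptance_rate)))
  invisible(x)
}

#' @export
length.abc_samples <- function(x) nrow(x$theta)

#' Weighted mean, variance and Monte-Carlo standard errors
#'
#' Self-normalized importance-sampling estimates of a scalar function's mean
#' and variance, with delta-method standard errors based on the effective
#' sample size.
#'
#' @param x draws (numeric vector).
#' @param w normalized weights.
#' @return list with `mean`, `var`, `se_mean`, `se_var`, `ess`.
#' @export
weighted_moments <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1 / length(x), length(x))
  w <- w / sum(w)
  m <- sum(w * x)
  v <- sum(w * (x - m)^2)
  ess <- 1 / sum(w^2)
  list(mean = m, var = v,
       se_mean = sqrt(v / ess),
       # SE of a variance estimate from ~ess effective draws (Gaussian case)
       se_var = v * sqrt(2 / max(ess - 1, 1)),
       ess = ess)
}

#' Weighted empirical quantiles
#'
#' Linear-interpolation quantiles of weighted draws.  With equal weights this
#' reduces exactly to the standard type-7 definition (plotting positions
#' \eqn{(i-1)/(n-1)}).
#'
#' @param x draws.
#' @param w weights (need not be normalized); NULL for equal weights.
#' @param probs probabilities in \[0, 1\].
#' @export
weighted_quantile <- function(x, w = NULL, probs = 0.5) {
  stopifnot(length(x) >= 1L)
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(w) == length(x), all(w >= 0), sum(w) > 0)
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w)
  # plotting positions generalizing type 7: p_i = C_{i-1} / (1 - w_n)
  denom <- 1 - w[length(w)]
  if (denom <= 0) return(rep(x[length(x)], length(probs)))
  pp <- (cw - w) / denom
  pp[pp > 1] <- 1
  stats::approx(pp, x, xout = probs, rule = 2, ties = "ordered")$y
}

#' Kolmogorov-Smirnov distance of (weighted) draws to a reference CDF
#'
#' Sup-distance between the weighted empirical CDF of the draws and a given
#' cumulative distribution function.
#'
#' @param x draws.
#' @param cdf vectorized reference CDF.
#' @param w weights (NULL for equal).
#' @export
ks_distance <- function(x, cdf, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w)
  Fx <- cdf(x)
  max(abs(cw - Fx), abs(c(0, cw[-length(cw)]) - Fx))
}
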