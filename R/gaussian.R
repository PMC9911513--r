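#' Gaussian density parameter pair
#'
#' @param mean mean.
#' @param variance nonnegative variance (0 only as a degenerate exact-limit
#'   marker).
#' @export
gaussian_density <- function(mean, variance) {
  stopifnot(is.numeric(mean), is.numeric(variance), variance >= 0)
  structure(list(mean = as.numeric(mean), variance = as.numeric(variance)),
            class = "gaussian_density")
}

#' @export
print.gaussian_density <- function(x, ...) {
  cat(sprintf("N(mean = %.6g, variance = %.6g)\n", x$mean, x$variance))
  invisible(x)
}

#' Exact conditioning in a Gaussian location model with a flat prior
#'
#' Consider \eqn{x = c\,a + w}, \eqn{w \sim N(0, V)}, with a scalar location
#' parameter \eqn{c} under the improper flat prior \eqn{\pi(c) \propto 1}.
#' Partition \eqn{x = (x_1, x_2)} and observe \eqn{x_2 = obs}.  The routine
#' returns the exact Gaussian posterior of \eqn{c} and the exact joint
#' Gaussian law of \eqn{(x_1, c)} given the observation, obtained by direct
#' joint-normal conditioning:
#' \deqn{c \mid x_2 \sim N(\hat c, \tau^2),\quad
#'   \hat c = \frac{a_2^\top V_{22}^{-1} obs}{a_2^\top V_{22}^{-1} a_2},\quad
#'   \tau^2 = (a_2^\top V_{22}^{-1} a_2)^{-1},}
#' and \eqn{x_1 \mid x_2} has mean \eqn{\hat c a_1 + V_{12} V_{22}^{-1}(obs -
#' \hat c a_2)} and covariance \eqn{V_{11\cdot 2} + b\,\tau^2\,b^\top} with
#' \eqn{b = a_1 - V_{12} V_{22}^{-1} a_2}.
#'
#' This is the package's independent oracle for closed-form ABC targets of
#' Gaussian location models (Markov chain and linear state-space examples).
#'
#' @param a1,a2 location coefficients of the target block and observed block.
#' @param V11,V12,V22 covariance blocks (V12 is `length(a1) x length(a2)`).
#' @param obs observed value of the second block.
#' @return list with `mean` and `cov` of \eqn{x_1 \mid x_2}, `c_mean`,
#'   `c_var` of \eqn{c \mid x_2}, and `cross` = Cov\eqn{(x_1, c \mid x_2)}.
#' @export
gaussian_flat_prior_condition <- function(a1, a2, V11, V12, V22, obs) {
  a1 <- as.numeric(a1); a2 <- as.numeric(a2); obs <- as.numeric(obs)
  V11 <- as.matrix(V11); V22 <- as.matrix(V22)
  V12 <- matrix(V12, nrow = length(a1), ncol = length(a2))
  stopifnot(length(obs) == length(a2))
  Vi_a <- solve(V22, a2)
  Vi_obs <- solve(V22, obs)
  prec_c <- drop(crossprod(a2, Vi_a))
  if (prec_c <= 0) stop("observed block carries no information about c")
  c_var <- 1 / prec_c
  c_mean <- drop(crossprod(a2, Vi_obs)) * c_var
  B <- V12 %*% solve(V22)         # regression of x1 on x2
  b <- a1 - drop(B %*% a2)
  cond_cov <- V11 - B %*% t(V12)
  mean1 <- c_mean * a1 + drop(B %*% (obs - c_mean * a2))
  cov1 <- cond_cov + c_var * tcrossprod(b)
  list(mean = mean1, cov = (cov1 + t(cov1)) / 2,
       c_mean = c_mean, c_var = c_var, cross = b * c_var)
}
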