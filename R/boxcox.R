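#' BoxCox power transformation
#'
#' \code{boxcox_transform} computes \eqn{(y^\lambda - 1)/\lambda} for
#' \eqn{\lambda \neq 0} and \eqn{\log y} for \eqn{\lambda = 0};
#' \code{boxcox_inverse} is its exact inverse.
#'
#' @param y strictly positive numeric vector.
#' @param lambda power parameter.
#' @return transformed (or back-transformed) numeric vector.
#' @export
boxcox_transform <- function(y, lambda) {
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("boxcox_transform: y must be strictly positive")
  }
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' @rdname boxcox_transform
#' @param t transformed values; for \eqn{\lambda > 0} they must exceed
#'   \eqn{-1/\lambda} (for \eqn{\lambda < 0}, lie below \eqn{-1/\lambda}),
#'   the range of the forward transform.
#' @export
boxcox_inverse <- function(t, lambda) {
  if (any(!is.finite(t))) stop("boxcox_inverse: non-finite input")
  if (abs(lambda) < 1e-12) return(exp(t))
  u <- lambda * t + 1
  if (any(u <= 0)) {
    stop("boxcox_inverse: value outside the range of the transform")
  }
  u^(1 / lambda)
}

#' Profile-likelihood estimate of the BoxCox exponent
#'
#' Maximises the BoxCox profile log-likelihood
#' \eqn{-n/2 \log(RSS(\lambda)/n) + (\lambda - 1)\sum \log y} over a bounded
#' interval, where \eqn{RSS(\lambda)} is the residual sum of squares of the
#' transformed outcome regressed on \code{X} (an intercept-only model when
#' \code{X} is \code{NULL}). A coarse grid locates the bracket; golden-section
#' search (\code{stats::optimize}) refines it.
#'
#' @param y strictly positive outcome vector.
#' @param X optional design matrix (without intercept column; one is added).
#' @param interval search bounds for lambda, default \code{c(-5, 5)}.
#' @param grid_n coarse grid size.
#' @return the estimated lambda (scalar).
#' @export
boxcox_lambda <- function(y, X = NULL, interval = c(-5, 5), grid_n = 101L) {
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("boxcox_lambda: y must be strictly positive")
  }
  if (stats::var(y) == 0) {
    stop("boxcox_lambda: y is constant; the profile likelihood is degenerate")
  }
  n <- length(y)
  Xd <- if (is.null(X)) matrix(1, n, 1) else cbind(1, as.matrix(X))
  if (nrow(Xd) != n) stop("boxcox_lambda: X and y lengths differ")
  slog <- sum(log(y))
  prof <- function(lambda) {
    t <- boxcox_transform(y, lambda)
    rss <- sum(stats::lm.fit(Xd, t)$residuals^2)
    if (rss <= 0) return(-Inf)
    -n / 2 * log(rss / n) + (lambda - 1) * slog
  }
  grid <- seq(interval[1], interval[2], length.out = grid_n)
  ll <- vapply(grid, prof, numeric(1))
  k <- which.max(ll)
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(grid_n, k + 1L)]
  stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-6)$maximum
}
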