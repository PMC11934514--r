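#' Replace compositional zeros by small positive values
#'
#' Diary-recorded time use can contain structural zeros ("did none of this on
#' the diary day") which preclude log-ratio analysis. Zeros are imputed below
#' a detection-limit-style cap (default 10 min) and every row is re-closed to
#' the daily total, leaving the ratios of originally observed parts unchanged
#' up to the common re-closure factor.
#'
#' Two methods are provided. \code{"lrEM"} (default) is an iterative
#' expectation-maximisation style routine on additive log-ratio coordinates:
#' zeros are initialised at \code{0.65 * cap}, then each part with censored
#' entries is repeatedly re-imputed from a linear regression of its alr
#' coordinate on the remaining coordinates (fitted on uncensored rows),
#' capped at \code{cap}, until the largest relative change of any imputed
#' value falls below \code{tol}. \code{"multiplicative"} is simple
#' multiplicative replacement (every zero set to \code{0.65 * cap}, observed
#' parts scaled down to preserve the total); it serves as a transparent
#' fallback and cross-check.
#'
#' @param x numeric matrix or data.frame of non-negative durations
#'   (rows = persons, columns = parts), each row summing to \code{total}.
#' @param cap maximum imputed value, minutes (default 10).
#' @param method \code{"lrEM"} or \code{"multiplicative"}.
#' @param tol relative-change convergence tolerance for \code{"lrEM"}.
#' @param maxit maximum lrEM iterations.
#' @param total row closure constant (1440 min/day).
#' @return numeric matrix of strictly positive durations, rows closed to
#'   \code{total}; imputed entries are all in \code{(0, cap]}.
#' @export
replace_zeros <- function(x, cap = 10, method = c("lrEM", "multiplicative"),
                          tol = 1e-6, maxit = 50L, total = DAY_MIN) {
  method <- match.arg(method)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (!is.numeric(cap) || length(cap) != 1L || cap <= 0) {
    stop("replace_zeros: cap must be a single positive number")
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("replace_zeros: durations must be finite and non-negative")
  }
  if (any(rowSums(m) == 0)) stop("replace_zeros: a row is entirely zero")
  zero <- m == 0
  if (!any(zero)) {
    return(closure(m, total))
  }
  n <- nrow(m); D <- ncol(m)
  if (D < 2L) stop("replace_zeros: need at least two parts")

  # cap-aware re-closure: imputed cells are pinned to <= cap and the
  # observed parts absorb the slack proportionally, so row ratios of
  # observed parts are preserved and rows sum to `total` exactly
  cap_close <- function(v, z) {
    v[z] <- pmin(v[z], cap)
    v[!z] <- v[!z] * (total - sum(v[z])) / sum(v[!z])
    v
  }

  # initialise all zeros at 0.65 * cap, keep observed values, re-close
  imp <- m
  imp[zero] <- 0.65 * cap
  for (i in which(rowSums(zero) > 0)) imp[i, ] <- cap_close(imp[i, ], zero[i, ])
  no_zero_rows <- rowSums(zero) == 0
  imp[no_zero_rows, ] <- closure(m[no_zero_rows, , drop = FALSE], total)

  if (method == "multiplicative") {
    # classic multiplicative replacement: fixed delta, shrink observed parts
    out <- m
    delta <- 0.65 * cap
    for (i in which(rowSums(zero) > 0)) {
      z <- zero[i, ]
      out[i, z] <- delta
      out[i, !z] <- m[i, !z] * (total - delta * sum(z)) / sum(m[i, !z])
    }
    out[rowSums(zero) == 0, ] <- closure(m[rowSums(zero) == 0, , drop = FALSE],
                                         total)
    return(out)
  }

  # lrEM: alr with a zero-free denominator part
  denom_ok <- colSums(zero) == 0
  if (!any(denom_ok)) {
    stop("replace_zeros: lrEM needs at least one part with no zeros")
  }
  d <- which(denom_ok)[1]
  cens_cols <- which(colSums(zero) > 0)

  for (it in seq_len(maxit)) {
    prev <- imp[zero]
    Y <- log(imp[, -d, drop = FALSE] / imp[, d])
    for (j in cens_cols) {
      cj <- which(seq_len(D)[-d] == j)
      obs <- !zero[, j]
      yj <- Y[, cj]
      Xj <- Y[, -cj, drop = FALSE]
      if (ncol(Xj) == 0L) {
        pred <- rep(mean(yj[obs]), sum(!obs))
      } else if (sum(obs) <= ncol(Xj) + 1L) {
        pred <- rep(mean(yj[obs]), sum(!obs))
      } else {
        fit <- stats::lm.fit(cbind(1, Xj[obs, , drop = FALSE]), yj[obs])
        pred <- cbind(1, Xj[!obs, , drop = FALSE]) %*% fit$coefficients
      }
      imp[!obs, j] <- pmin(imp[!obs, d] * exp(pred), cap)
    }
    for (i in which(rowSums(zero) > 0)) {
      imp[i, ] <- cap_close(imp[i, ], zero[i, ])
    }
    delta_rel <- max(abs(imp[zero] - prev) / prev)
    if (delta_rel < tol) break
  }
  imp
}

#' Isometric log-ratio basis from a sequential binary partition
#'
#' Builds the orthonormal pivot (Helmert-type) contrast matrix for the given
#' part order: coordinate \eqn{i} balances part \eqn{i} against the geometric
#' mean of the parts after it. Any valid sequential binary partition gives an
#' orthonormal basis differing only by rotation; model fit and predictions do
#' not depend on the choice.
#'
#' @param parts character vector of (unique) part names; its order defines
#'   the pivots.
#' @return a \code{(D-1) x D} matrix \code{V} with rows orthonormal and
#'   summing to zero, columns named by \code{parts}.
#' @export
make_sbp <- function(parts = time_parts()) {
  if (anyDuplicated(parts)) stop("make_sbp: duplicate part names")
  D <- length(parts)
  if (D < 2L) stop("make_sbp: need at least two parts")
  V <- matrix(0, D - 1L, D, dimnames = list(paste0("z", seq_len(D - 1L)),
                                            parts))
  for (i in seq_len(D - 1L)) {
    r <- D - i                     # number of parts after the pivot
    a <- sqrt(r / (r + 1))
    V[i, i] <- a
    V[i, (i + 1L):D] <- -a / r
  }
  V
}

#' Isometric log-ratio coordinates
#'
#' Maps strictly positive compositions to unconstrained real coordinates
#' \code{z = V %*% log(x)}. The result is invariant to (row-wise) closure.
#'
#' @param x positive numeric vector or matrix (rows = compositions); columns
#'   must match the basis parts (by name when named).
#' @param sbp basis matrix from \code{\link{make_sbp}}.
#' @return numeric matrix of ilr coordinates (one row per composition).
#' @export
ilr_transform <- function(x, sbp = make_sbp()) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  if (!is.null(colnames(x)) && !is.null(colnames(sbp))) {
    if (!all(colnames(sbp) %in% colnames(x))) {
      stop("ilr_transform: composition lacks basis part(s)")
    }
    x <- x[, colnames(sbp), drop = FALSE]
  }
  if (ncol(x) != ncol(sbp)) stop("ilr_transform: dimension mismatch")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("ilr_transform: parts must be strictly positive (run replace_zeros first)")
  }
  z <- log(x) %*% t(sbp)
  colnames(z) <- rownames(sbp)
  z
}

#' Inverse isometric log-ratio transform
#'
#' @param z numeric vector or matrix of ilr coordinates.
#' @param sbp basis matrix used for the forward transform.
#' @param total closure constant for the returned composition.
#' @return matrix of positive compositions, rows closed to \code{total}.
#' @export
ilr_inverse <- function(z, sbp = make_sbp(), total = DAY_MIN) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  if (ncol(z) != nrow(sbp)) stop("ilr_inverse: dimension mismatch")
  if (any(!is.finite(z))) stop("ilr_inverse: non-finite coordinates")
  x <- exp(z %*% sbp)
  colnames(x) <- colnames(sbp)
  closure(x, total)
}

#' Closed geometric mean of a sample of compositions
#'
#' @param x positive matrix, rows = compositions.
#' @param total closure constant.
#' @return named vector: the compositional mean closed to \code{total}.
#' @export
compositional_mean <- function(x, total = DAY_MIN) {
  m <- as.matrix(x)
  if (nrow(m) == 0L) stop("compositional_mean: empty sample")
  if (any(m <= 0)) stop("compositional_mean: parts must be strictly positive")
  g <- exp(colMeans(log(m)))
  closure(g, total)
}

#' Reference profile: the "average day" used as the reallocation origin
#'
#' The time-use reference is the compositional (closed geometric) mean
#' rounded onto the 10-min grid by largest-remainder apportionment so the
#' parts still sum to exactly 1440; the diet reference is each serving-score
#' mean rounded (half away from zero) to the nearest integer.
#'
#' @param time positive duration matrix (zero-replaced), or a precomputed
#'   compositional-mean vector.
#' @param diet data.frame/matrix with columns \code{fruit_veg},
#'   \code{discretionary}, \code{ssb}, or a length-3 mean vector.
#' @param step time rounding grid, minutes.
#' @return object of class \code{reference_profile}: list with \code{time}
#'   (named, multiples of \code{step}, summing to 1440) and \code{diet}
#'   (named integers).
#' @export
reference_profile <- function(time, diet, step = 10) {
  tm <- if (is.matrix(time) || is.data.frame(time)) {
    compositional_mean(as_part_matrix(time, time_parts(), "reference_profile"))
  } else {
    if (length(time) != 7L) stop("reference_profile: need 7 time parts")
    stats::setNames(as.numeric(time), if (is.null(names(time))) time_parts()
                    else names(time))[time_parts()]
  }
  dm <- if (is.matrix(diet) || is.data.frame(diet)) {
    colMeans(as_part_matrix(diet, diet_scores(), "reference_profile"))
  } else {
    if (length(diet) != 3L) stop("reference_profile: need 3 diet scores")
    stats::setNames(as.numeric(diet), if (is.null(names(diet))) diet_scores()
                    else names(diet))[diet_scores()]
  }
  out <- list(
    time = largest_remainder_round(tm, step = step, total = DAY_MIN),
    diet = stats::setNames(round_half_away(dm), diet_scores())
  )
  class(out) <- "reference_profile"
  out
}

#' @export
print.reference_profile <- function(x, ...) {
  cat("Reference profile (zero-difference origin)\n")
  cat("  Time use (min/day):\n")
  print(x$time)
  cat("  Diet (serves/day):\n")
  print(x$diet)
  invisible(x)
}

#' Aitchison distance between two compositions
#'
#' Euclidean distance between the centred log-ratio images; equals the
#' Euclidean distance between ilr coordinates under any orthonormal basis.
#'
#' @param a,b strictly positive compositions of equal length.
#' @return non-negative scalar.
#' @export
aitchison_dist <- function(a, b) {
  if (length(a) != length(b)) stop("aitchison_dist: length mismatch")
  if (any(a <= 0) || any(b <= 0)) stop("aitchison_dist: positive parts required")
  ca <- log(a) - mean(log(a))
  cb <- log(b) - mean(log(b))
  sqrt(sum((ca - cb)^2))
}
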