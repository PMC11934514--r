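#' Canonical part, score and item names
#'
#' Column names used throughout the package: the seven 24-h time-use
#' behaviours (minutes/day, closing to 1440), the three diet serving scores
#' with their maxima, the raw questionnaire items they are built from, the
#' eight PedsQL physical-functioning items, and the covariates.
#'
#' @return character vectors (or, for \code{diet_items}, a named list of
#'   item names per food group; for \code{diet_score_max}, a named numeric
#'   vector).
#' @name equiv24-names
NULL

#' @rdname equiv24-names
#' @export
time_parts <- function() {
  c("sleep", "self_care", "screen", "quiet", "physical_activity",
    "school", "domestic_social")
}

#' @rdname equiv24-names
#' @export
diet_scores <- function() c("fruit_veg", "discretionary", "ssb")

#' @rdname equiv24-names
#' @export
diet_score_max <- function() {
  c(fruit_veg = 9, discretionary = 12, ssb = 6)
}

#' @rdname equiv24-names
#' @export
diet_items <- function() {
  list(
    fruit_veg = c("fruit", "cooked_veg", "raw_veg"),
    discretionary = c("pie_burger", "hot_chips", "savoury_snacks",
                      "sweet_snacks"),
    ssb = c("energy_drink", "soft_drink")
  )
}

#' @rdname equiv24-names
#' @export
pedsql_items <- function() paste0("pf_", 1:8)

#' @rdname equiv24-names
#' @export
covariate_names <- function() c("age", "sex", "sep")

DAY_MIN <- 1440

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; questionnaire conventions round
#' 0.5 upwards (and -0.5 downwards).
#'
#' @param x numeric vector.
#' @return rounded numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

#' Largest-remainder rounding onto a grid with a fixed total
#'
#' Rounds each element of \code{x} to a multiple of \code{step} such that the
#' rounded values sum exactly to \code{total}: integer quotas are floored and
#' the shortfall is distributed one step at a time to the elements with the
#' largest fractional remainders (ties broken by position, first wins).
#'
#' @param x non-negative numeric vector.
#' @param step grid resolution (e.g. 10 minutes).
#' @param total required sum of the result (e.g. 1440).
#' @return numeric vector of multiples of \code{step} summing to \code{total}.
#' @export
largest_remainder_round <- function(x, step = 10, total = DAY_MIN) {
  stopifnot(is.numeric(x), length(x) >= 1L, all(is.finite(x)), step > 0)
  if (any(x < 0)) stop("largest_remainder_round: negative values")
  units_total <- total / step
  if (abs(units_total - round(units_total)) > 1e-8) {
    stop("largest_remainder_round: total is not a multiple of step")
  }
  q <- x / step
  base <- floor(q + 1e-9)           # guard against 17.999999999 quotas
  rem <- q - base
  short <- round(units_total) - sum(base)
  if (short < 0) stop("largest_remainder_round: floored quotas exceed total")
  if (short > 0) {
    take <- order(-rem)[seq_len(short)]  # stable: ties keep original order
    base[take] <- base[take] + 1
  }
  out <- base * step
  names(out) <- names(x)
  out
}

#' Close a composition to a fixed total
#'
#' @param x numeric vector or matrix (rows are compositions) of positive parts.
#' @param total closure constant, 1440 min/day by default.
#' @return object of the same shape rescaled so (row) sums equal \code{total}.
#' @export
closure <- function(x, total = DAY_MIN) {
  if (is.matrix(x)) {
    sums <- rowSums(x)
    if (any(!is.finite(sums)) || any(sums <= 0)) {
      stop("closure: rows must have positive finite sums")
    }
    x * (total / sums)
  } else {
    s <- sum(x)
    if (!is.finite(s) || s <= 0) stop("closure: sum must be positive")
    x * (total / s)
  }
}

# coerce a data.frame/matrix to a plain numeric matrix with given columns,
# with informative errors naming the missing columns
as_part_matrix <- function(data, cols, context = "input") {
  missing_cols <- setdiff(cols, colnames(data))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s) %s", context,
                 paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(as.data.frame(data)[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

# first offending row/column for validators
first_bad <- function(bad_mat) {
  idx <- which(bad_mat, arr.ind = TRUE)[1, , drop = TRUE]
  list(row = unname(idx[1]), col = unname(idx[2]))
}
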