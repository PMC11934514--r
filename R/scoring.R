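#' Diet serving scores from questionnaire items
#'
#' Each of the nine previous-day intake questions is coded 0 = "Not at all",
#' 1 = "Once", 2 = "Twice", 3 = "More than twice", and each reported instance
#' is treated as one serving. Items are summed within food group: fruit and
#' vegetables (3 items, score 0-9), discretionary foods (4 items, 0-12) and
#' sugar-sweetened beverages (2 items, 0-6). Any missing item makes that
#' food-group score missing (records with missing diet are dropped from the
#' analytic sample downstream).
#'
#' @param items data.frame or matrix with the nine item columns named as in
#'   \code{diet_items()} (fruit, cooked_veg, raw_veg, pie_burger, hot_chips,
#'   savoury_snacks, sweet_snacks, energy_drink, soft_drink); values in
#'   \code{0:3} or \code{NA}.
#' @return data.frame with columns \code{fruit_veg}, \code{discretionary},
#'   \code{ssb} (integer serves, \code{NA} when any component item missing).
#' @export
score_diet <- function(items) {
  groups <- diet_items()
  m <- as_part_matrix(items, unlist(groups), "score_diet")
  ok <- is.na(m) | (m %in% 0:3 & m == floor(m))
  if (!all(ok)) {
    bad <- first_bad(!ok)
    stop(sprintf(
      "score_diet: invalid response %s at row %d, column '%s' (allowed: 0-3 or missing)",
      format(m[bad$row, bad$col]), bad$row, colnames(m)[bad$col]))
  }
  out <- lapply(groups, function(cols) {
    rowSums(m[, cols, drop = FALSE])   # NA if any item missing
  })
  as.data.frame(out)
}

#' PedsQL physical-functioning score from item responses
#'
#' The eight teen physical-functioning items are coded 0 = "Never" to
#' 4 = "Almost always" (higher = more of a problem). The score is the
#' standard linear reverse mapping of the mean item response onto 0-100,
#' \code{25 * (4 - mean)}, so higher scores indicate better functioning.
#' The score is missing when five or more items are missing.
#'
#' @param items data.frame or matrix with columns \code{pf_1}..\code{pf_8};
#'   values in \code{0:4} or \code{NA}.
#' @return numeric vector of scores in \code{[0, 100]}, \code{NA} where the
#'   missing-item rule fires.
#' @export
score_pedsql <- function(items) {
  m <- as_part_matrix(items, pedsql_items(), "score_pedsql")
  ok <- is.na(m) | (m %in% 0:4 & m == floor(m))
  if (!all(ok)) {
    bad <- first_bad(!ok)
    stop(sprintf(
      "score_pedsql: invalid response %s at row %d, column '%s' (allowed: 0-4 or missing)",
      format(m[bad$row, bad$col]), bad$row, colnames(m)[bad$col]))
  }
  n_miss <- rowSums(is.na(m))
  score <- 25 * (4 - rowMeans(m, na.rm = TRUE))
  score[n_miss >= 5] <- NA_real_
  score[is.nan(score)] <- NA_real_
  score
}

#' Score a raw cohort table
#'
#' Adds the three diet serving scores and the physical-functioning score to a
#' person-level table holding the raw questionnaire items.
#'
#' @param data data.frame with the nine diet item columns and the eight
#'   PedsQL item columns (see \code{\link{score_diet}},
#'   \code{\link{score_pedsql}}).
#' @return \code{data} with columns \code{fruit_veg}, \code{discretionary},
#'   \code{ssb} and \code{pf} appended.
#' @export
score_cohort <- function(data) {
  d <- score_diet(data)
  data$fruit_veg <- d$fruit_veg
  data$discretionary <- d$discretionary
  data$ssb <- d$ssb
  data$pf <- score_pedsql(data)
  data
}
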