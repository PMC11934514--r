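#' Compositional block F-test
#'
#' Tests whether the overall 24-h time-use composition is associated with
#' physical functioning: the partial F statistic comparing the full model to
#' the nested model with all six ilr coordinates removed,
#' \eqn{F = ((RSS_0 - RSS_1)/6) / (RSS_1 / df_{res})}. The statistic is
#' invariant to the ilr basis since any orthonormal basis spans the same
#' column space.
#'
#' @param object a \code{\link{pf_model}} fit.
#' @return list of class \code{pf_block_test}: \code{F}, \code{df1},
#'   \code{df2}, \code{p}.
#' @export
composition_ftest <- function(object) {
  stopifnot(inherits(object, "pf_model"))
  if (object$df_residual <= 0) {
    stop("composition_ftest: no residual degrees of freedom")
  }
  frame <- object$lm$model
  zcols <- paste0("z", seq_len(nrow(object$sbp)))
  keep <- setdiff(names(frame), c("t_pf", zcols))
  X_red <- cbind(1, as.matrix(frame[, keep, drop = FALSE]))
  rss_red <- sum(stats::lm.fit(X_red, frame$t_pf)$residuals^2)
  rss_full <- sum(object$lm$residuals^2)
  if (rss_red < rss_full - 1e-8) {
    stop("composition_ftest: reduced model is not nested in the full model")
  }
  df1 <- length(zcols)
  df2 <- object$df_residual
  F <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  out <- list(F = F, df1 = df1, df2 = df2,
              p = stats::pf(F, df1, df2, lower.tail = FALSE))
  class(out) <- "pf_block_test"
  out
}

#' @export
print.pf_block_test <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.3f, p = %.4g\n", x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Standardised regression coefficients
#'
#' For each requested predictor, \code{std_beta = b * sd(x) / sd(t)} where
#' \code{b} is the raw coefficient, \code{sd(x)} the analytic-sample SD of
#' the predictor and \code{sd(t)} the SD of the BoxCox-transformed outcome.
#' The p-value is the coefficient's t-test p from the fitted model.
#'
#' @param object a \code{\link{pf_model}} fit.
#' @param variables predictors to report; defaults to the three diet scores.
#' @return data.frame with columns \code{variable}, \code{beta},
#'   \code{std_beta}, \code{p}.
#' @export
standardized_betas <- function(object, variables = diet_scores()) {
  stopifnot(inherits(object, "pf_model"))
  cf <- summary(object$lm)$coefficients
  bad <- setdiff(variables, rownames(cf))
  if (length(bad)) {
    stop("standardized_betas: unknown variable(s) ", paste(bad, collapse = ", "))
  }
  sx <- object$sds[variables]
  if (any(sx == 0)) {
    stop("standardized_betas: zero-variance predictor ",
         paste(variables[sx == 0], collapse = ", "))
  }
  sy <- object$sds[["t_pf"]]
  data.frame(
    variable = variables,
    beta = cf[variables, "Estimate"],
    std_beta = cf[variables, "Estimate"] * sx / sy,
    p = cf[variables, "Pr(>|t|)"],
    row.names = NULL
  )
}

#' Screen for sex-by-behaviour interactions
#'
#' Adds sex-interaction terms to the full model block by block -- the six ilr
#' coordinates jointly, then each diet score singly -- and reports the
#' partial F-test of each block of interaction terms. Non-significant
#' interactions justify analysing the sexes together.
#'
#' @param object a \code{\link{pf_model}} fit.
#' @return data.frame with columns \code{block}, \code{df1}, \code{df2},
#'   \code{F}, \code{p}.
#' @export
sex_interaction_screen <- function(object) {
  stopifnot(inherits(object, "pf_model"))
  frame <- object$lm$model
  if (length(unique(frame$sex)) < 2L) {
    stop("sex_interaction_screen: single-sex sample; interactions inestimable")
  }
  zcols <- paste0("z", seq_len(nrow(object$sbp)))
  X_full <- cbind(1, as.matrix(frame[, setdiff(names(frame), "t_pf")]))
  y <- frame$t_pf
  rss_full <- sum(stats::lm.fit(X_full, y)$residuals^2)
  df_full <- nrow(frame) - ncol(X_full)

  blocks <- c(list(composition = zcols), as.list(stats::setNames(
    diet_scores(), diet_scores())))
  res <- lapply(names(blocks), function(bn) {
    cols <- blocks[[bn]]
    inter <- as.matrix(frame[, cols, drop = FALSE]) * frame$sex
    colnames(inter) <- paste0("sex_x_", cols)
    X_aug <- cbind(X_full, inter)
    fit_aug <- stats::lm.fit(X_aug, y)
    rank_added <- fit_aug$rank - qr(X_full)$rank
    if (rank_added < length(cols)) {
      stop("sex_interaction_screen: interaction block '", bn,
           "' is collinear with the main effects")
    }
    rss_aug <- sum(fit_aug$residuals^2)
    df2 <- nrow(frame) - ncol(X_aug)
    F <- ((rss_full - rss_aug) / length(cols)) / (rss_aug / df2)
    data.frame(block = bn, df1 = length(cols), df2 = df2, F = F,
               p = stats::pf(F, length(cols), df2, lower.tail = FALSE))
  })
  do.call(rbind, res)
}
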