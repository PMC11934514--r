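#' Grid of feasible time reallocations
#'
#' Enumerates every zero-sum vector of per-behaviour minute changes with each
#' component on the \code{step}-minute grid within \code{[-radius, radius]}
#' (a per-behaviour, Chebyshev-style radius). Zero sum keeps the perturbed
#' day closed to 1440 min. Rows are returned in lexicographic order of the
#' part columns, so the enumeration is deterministic and byte-stable.
#'
#' @param reference optional \code{\link{reference_profile}}; when supplied,
#'   vectors leaving any behaviour non-positive are dropped.
#' @param step grid increment, minutes (default 10).
#' @param radius per-behaviour bound, minutes (default 30); must be a
#'   multiple of \code{step}.
#' @param parts part names (columns of the result).
#' @return numeric matrix, one row per reallocation, columns named by part.
#' @export
make_time_grid <- function(reference = NULL, step = 10, radius = 30,
                           parts = time_parts()) {
  if (step <= 0 || radius < 0) stop("make_time_grid: step > 0, radius >= 0 required")
  if (abs(radius / step - round(radius / step)) > 1e-9) {
    stop("make_time_grid: radius must be a multiple of step")
  }
  D <- length(parts)
  levels <- seq(-radius, radius, by = step)
  L <- length(levels)

  # grow columns left to right, pruning prefixes whose remaining parts
  # cannot cancel the running sum; expansion order preserves lexicographic
  # row ordering
  M <- matrix(0, nrow = 1, ncol = 0)
  for (k in seq_len(D - 1L)) {
    n <- nrow(M)
    M <- cbind(M[rep(seq_len(n), each = L), , drop = FALSE],
               rep(levels, times = n))
    rem <- D - k
    M <- M[abs(rowSums(M)) <= rem * radius + 1e-9, , drop = FALSE]
  }
  last <- -rowSums(M)
  G <- cbind(M, last)[abs(last) <= radius + 1e-9, , drop = FALSE]
  colnames(G) <- parts
  if (!is.null(reference)) {
    ref <- reference$time[parts]
    G <- G[rowSums(sweep(G, 2, ref, "+") <= 0) == 0, , drop = FALSE]
  }
  G
}

#' Grid of feasible diet serving changes
#'
#' The Cartesian product of per-score changes from -1.5 to +1.5 serves in
#' 0.5-serve increments, filtered so each perturbed score stays non-negative
#' and within its questionnaire maximum (9 / 12 / 6 serves). With the
#' reference at 1 SSB serve this leaves SSB changes of -1 to +1.5, matching
#' the non-negativity restriction.
#'
#' @param reference a \code{\link{reference_profile}} (its \code{diet}
#'   component supplies the starting serves).
#' @param span largest absolute change, serves.
#' @param step_serves grid increment, serves.
#' @return numeric matrix with columns \code{fruit_veg},
#'   \code{discretionary}, \code{ssb}, rows in lexicographic order.
#' @export
make_diet_grid <- function(reference, span = 1.5, step_serves = 0.5) {
  ref <- reference$diet[diet_scores()]
  mx <- diet_score_max()
  levels <- seq(-span, span, by = step_serves)
  feas <- lapply(diet_scores(), function(s) {
    lv <- levels[ref[[s]] + levels >= -1e-9 & ref[[s]] + levels <= mx[[s]] + 1e-9]
    lv
  })
  names(feas) <- diet_scores()
  G <- as.matrix(expand.grid(rev(feas), KEEP.OUT.ATTRS = FALSE))
  G <- G[, diet_scores(), drop = FALSE]
  G[order(G[, 1], G[, 2], G[, 3]), , drop = FALSE]
}

# linear predictor (transformed scale) at a single profile
pf_linpred <- function(object, time_comp, diet, covariates) {
  z <- drop(ilr_transform(time_comp, object$sbp))
  cf <- object$coef
  unname(cf[1] + sum(cf[paste0("z", seq_along(z))] * z) +
           sum(cf[diet_scores()] * diet[diet_scores()]) +
           sum(cf[covariate_names()] * covariates[covariate_names()]))
}

#' Predicted physical-functioning difference for one behaviour change
#'
#' Applies a time-reallocation vector and a diet change to the reference
#' profile, predicts both profiles with covariates held constant, and
#' returns the difference on the original 0-100 scale (both predictions
#' back-transformed from the BoxCox scale). On the transformed scale the
#' model is linear, so time and diet contributions are exactly additive
#' there; after back-transformation they need not be.
#'
#' @param object a \code{\link{pf_model}} fit.
#' @param reference a \code{\link{reference_profile}}.
#' @param time_delta named (or canonically ordered) length-7 vector of
#'   minute changes summing to 0.
#' @param diet_delta named length-3 vector of serving changes.
#' @param covariates named vector (\code{age}, \code{sex}, \code{sep});
#'   default: analytic-sample mean age and SEP, modal sex, as stored in the
#'   fit.
#' @return scalar predicted difference, PedsQL points.
#' @export
predict_difference <- function(object, reference, time_delta, diet_delta,
                               covariates = NULL) {
  stopifnot(inherits(object, "pf_model"))
  if (is.null(covariates)) covariates <- object$covariate_fix
  # unnamed deltas are read in the reference's canonical part order, not the
  # (possibly permuted) basis order
  parts <- names(reference$time)
  td <- if (is.null(names(time_delta))) {
    stats::setNames(as.numeric(time_delta), parts)
  } else time_delta[parts]
  dd <- if (is.null(names(diet_delta))) {
    stats::setNames(as.numeric(diet_delta), diet_scores())
  } else diet_delta[diet_scores()]
  if (abs(sum(td)) > 1e-6) stop("predict_difference: time deltas must sum to 0")
  ref_t <- reference$time[parts]
  pert <- ref_t + td
  if (any(pert <= 0)) {
    stop("predict_difference: perturbed composition has a non-positive part")
  }
  t1 <- pf_linpred(object, pert, reference$diet + dd, covariates)
  t0 <- pf_linpred(object, ref_t, reference$diet, covariates)
  (boxcox_inverse(t1, object$lambda) - object$shift) -
    (boxcox_inverse(t0, object$lambda) - object$shift)
}

#' Enumerate all equivalent behaviour-change options
#'
#' Scores every combination of feasible time reallocation
#' (\code{\link{make_time_grid}}) and diet change
#' (\code{\link{make_diet_grid}}) by its model-predicted difference in
#' physical functioning relative to the reference profile (covariates held
#' at their mean/mode), and assigns each combination to a target band:
#' band \eqn{\Delta} collects combinations with
#' \code{|difference - delta| < tolerance}. With targets spaced 0.5 apart
#' and the default tolerance of 0.25 the bands are disjoint and exhaustive
#' over \code{[min target - 0.25, max target + 0.25]}.
#'
#' The computation is vectorised: time and diet contributions are additive
#' on the BoxCox scale, so the full difference surface is an outer sum,
#' back-transformed in chunks.
#'
#' @param object a \code{\link{pf_model}} fit.
#' @param reference a \code{\link{reference_profile}}.
#' @param step,radius time-grid settings (minutes).
#' @param targets band centres, PedsQL points (default \eqn{\pm}0.5 to
#'   \eqn{\pm}2.5).
#' @param tolerance half-width of each band; must not exceed half the
#'   smallest spacing between targets.
#' @param covariates optional named covariate vector (see
#'   \code{\link{predict_difference}}).
#' @param keep_bands bands whose member rows are materialised in
#'   \code{options} (default: all targets). Counts are always computed for
#'   every band; restricting this only limits the extracted rows, which for
#'   strong models can run to millions.
#' @param keep_full keep the full difference matrix (time grid x diet grid)
#'   in the result; memory-heavy for the default grids.
#' @param chunk number of diet columns processed per block.
#' @return object of class \code{option_table}: list with \code{options}
#'   (data.frame of banded rows: the ten per-behaviour deltas, the predicted
#'   \code{diff} and its \code{band}), \code{counts} (rows per band,
#'   including \code{none}), the grids, the reference, and scalars
#'   \code{t0}/\code{y0} (transformed/back-transformed reference
#'   prediction).
#' @export
enumerate_options <- function(object, reference, step = 10, radius = 30,
                              targets = c(-rev(seq(0.5, 2.5, 0.5)),
                                          seq(0.5, 2.5, 0.5)),
                              tolerance = 0.25, covariates = NULL,
                              keep_bands = NULL, keep_full = FALSE,
                              chunk = 32L) {
  stopifnot(inherits(object, "pf_model"))
  targets <- sort(unique(targets))
  if (length(targets) == 0) stop("enumerate_options: no targets")
  if (length(targets) > 1 && tolerance > min(diff(targets)) / 2 + 1e-12) {
    stop("enumerate_options: tolerance exceeds half the target spacing; bands would overlap")
  }
  if (is.null(covariates)) covariates <- object$covariate_fix
  if (is.null(keep_bands)) keep_bands <- targets
  if (!all(keep_bands %in% targets)) {
    stop("enumerate_options: keep_bands must be a subset of targets")
  }
  parts <- names(reference$time)

  tg <- make_time_grid(reference, step = step, radius = radius, parts = parts)
  dg <- make_diet_grid(reference)
  if (nrow(tg) == 0 || nrow(dg) == 0) stop("enumerate_options: empty grid")

  cf <- object$coef
  beta_z <- cf[paste0("z", seq_len(nrow(object$sbp)))]
  beta_d <- cf[diet_scores()]

  ref_t <- reference$time[parts]
  z_ref <- drop(ilr_transform(ref_t, object$sbp))
  t0 <- pf_linpred(object, ref_t, reference$diet, covariates)
  y0 <- boxcox_inverse(t0, object$lambda) - object$shift

  # time contribution: ilr of each perturbed day, against the reference
  comp <- sweep(tg, 2, ref_t, "+")
  a <- drop((log(comp) %*% t(object$sbp)) %*% beta_z) - sum(z_ref * beta_z)
  b <- drop(dg %*% beta_d)

  nt <- length(a); nd <- length(b)
  res_i <- vector("list", ceiling(nd / chunk))
  res_j <- res_i; res_d <- res_i; res_b <- res_i
  full <- if (keep_full) matrix(NA_real_, nt, nd) else NULL
  counts <- stats::setNames(numeric(length(targets) + 1),
                            c(as.character(targets), "none"))
  ci <- 0L
  for (j0 in seq(1L, nd, by = chunk)) {
    jj <- j0:min(nd, j0 + chunk - 1L)
    tmat <- outer(a, b[jj], "+") + t0
    dmat <- boxcox_inverse(tmat, object$lambda) - object$shift - y0
    if (keep_full) full[, jj] <- dmat
    band <- matrix(NA_real_, nrow(dmat), ncol(dmat))
    for (tgt in targets) {
      hit <- abs(dmat - tgt) < tolerance
      band[hit] <- tgt
    }
    for (k in seq_along(targets)) {
      counts[k] <- counts[k] + sum(band == targets[k], na.rm = TRUE)
    }
    band[!(band %in% keep_bands)] <- NA_real_
    sel <- which(!is.na(band), arr.ind = TRUE)
    if (nrow(sel)) {
      ci <- ci + 1L
      res_i[[ci]] <- sel[, 1]
      res_j[[ci]] <- jj[sel[, 2]]
      res_d[[ci]] <- dmat[sel]
      res_b[[ci]] <- band[sel]
    }
  }
  i <- as.integer(unlist(res_i)); j <- as.integer(unlist(res_j))
  dv <- as.numeric(unlist(res_d)); bv <- as.numeric(unlist(res_b))
  ord <- order(i, j)
  options_df <- if (length(i)) {
    data.frame(tg[i[ord], , drop = FALSE], dg[j[ord], , drop = FALSE],
               diff = dv[ord], band = bv[ord], row.names = NULL)
  } else {
    empty <- as.data.frame(matrix(numeric(0), 0, length(parts) + 3 + 2))
    names(empty) <- c(parts, diet_scores(), "diff", "band")
    empty
  }
  counts["none"] <- nt * nd - sum(counts[seq_along(targets)])

  out <- list(options = options_df, counts = counts, targets = targets,
              keep_bands = keep_bands,
              tolerance = tolerance, time_grid = tg, diet_grid = dg,
              reference = reference, covariates = covariates,
              t0 = t0, y0 = y0, n_total = nt * nd, full = full)
  class(out) <- "option_table"
  out
}

#' @export
print.option_table <- function(x, ...) {
  cat(sprintf("Option table: %d time reallocations x %d diet changes = %s combinations\n",
              nrow(x$time_grid), nrow(x$diet_grid),
              format(x$n_total, big.mark = ",")))
  cat(sprintf("Bands (centre +/- %.2g PedsQL points):\n", x$tolerance))
  print(x$counts)
  invisible(x)
}

#' Per-behaviour distribution of options within a band
#'
#' For every one of the ten behaviours (seven time-use, three diet), the
#' percentage of the band's options at each change level -- the numbers
#' behind the stacked bar plots of equivalent behaviour-change options.
#'
#' @param table an \code{\link{enumerate_options}} result.
#' @param band target band centre (e.g. \code{2.5}).
#' @return data.frame of class \code{option_summary} with columns
#'   \code{behaviour}, \code{delta}, \code{n}, \code{pct}; percentages sum
#'   to 100 within each behaviour. Zero rows (with attribute
#'   \code{n_options = 0}) when the band is empty.
#' @export
summarize_options <- function(table, band) {
  stopifnot(inherits(table, "option_table"))
  if (!band %in% table$targets) {
    stop("summarize_options: band must be one of the enumerated targets")
  }
  if (!band %in% table$keep_bands) {
    stop("summarize_options: band ", band,
         " was not materialised (see keep_bands)")
  }
  sub <- table$options[table$options$band == band, , drop = FALSE]
  behaviours <- c(colnames(table$time_grid), diet_scores())
  if (nrow(sub) == 0) {
    out <- data.frame(behaviour = character(0), delta = numeric(0),
                      n = integer(0), pct = numeric(0))
  } else {
    out <- do.call(rbind, lapply(behaviours, function(bh) {
      tab <- table(sub[[bh]])
      data.frame(behaviour = bh, delta = as.numeric(names(tab)),
                 n = as.integer(tab), pct = 100 * as.integer(tab) / nrow(sub),
                 row.names = NULL)
    }))
  }
  attr(out, "band") <- band
  attr(out, "n_options") <- nrow(sub)
  class(out) <- c("option_summary", class(out))
  out
}

#' @export
plot.option_summary <- function(x, ...) {
  if (attr(x, "n_options") == 0) {
    stop("plot.option_summary: empty band")
  }
  m <- stats::xtabs(pct ~ delta + behaviour, data = x)
  cols <- grDevices::hcl.colors(nrow(m), "RdYlBu")
  op <- graphics::par(mar = c(9, 4, 3, 7), xpd = TRUE)
  on.exit(graphics::par(op))
  graphics::barplot(m, col = cols, las = 2,
                    ylab = "% of equivalent options",
                    main = sprintf("Band %+.1f PedsQL points (%d options)",
                                   attr(x, "band"), attr(x, "n_options")))
  graphics::legend("topright", inset = c(-0.15, 0), legend = rownames(m),
                   fill = cols, title = "change", cex = 0.7)
  invisible(x)
}

#' Sequential interactive filtering of an option band
#'
#' Mirrors the decision-tool flow: the user fixes one behaviour change at a
#' time and the remaining option set shrinks to the rows consistent with
#' every choice so far. The deltas offered for an unselected behaviour are
#' exactly the distinct values present in the remaining subset, so a chosen
#' path can never empty the set. Filtering is order-invariant.
#'
#' \code{selection_state} starts a session on one band;
#' \code{available_options} lists the offerable deltas per unselected
#' behaviour; \code{select_option} applies one choice.
#'
#' @param table an \code{\link{enumerate_options}} result.
#' @param band target band centre.
#' @return \code{selection_state}: object with \code{choices} (named list in
#'   selection order) and \code{remaining} (the consistent option rows).
#' @export
selection_state <- function(table, band) {
  stopifnot(inherits(table, "option_table"))
  sub <- table$options[table$options$band == band, , drop = FALSE]
  if (nrow(sub) == 0) stop("selection_state: band is empty")
  behaviours <- c(colnames(table$time_grid), diet_scores())
  out <- list(remaining = sub, behaviours = behaviours, band = band,
              choices = list())
  class(out) <- "selection_state"
  out
}

#' @rdname selection_state
#' @param state a \code{selection_state}.
#' @export
available_options <- function(state) {
  stopifnot(inherits(state, "selection_state"))
  open <- setdiff(state$behaviours, names(state$choices))
  lapply(stats::setNames(open, open), function(bh) {
    sort(unique(state$remaining[[bh]]))
  })
}

#' @rdname selection_state
#' @param behaviour behaviour to fix (one of the ten).
#' @param delta chosen change (must be offered by
#'   \code{available_options}).
#' @export
select_option <- function(state, behaviour, delta) {
  stopifnot(inherits(state, "selection_state"))
  if (!behaviour %in% state$behaviours) {
    stop("select_option: unknown behaviour '", behaviour, "'")
  }
  if (behaviour %in% names(state$choices)) {
    stop("select_option: '", behaviour, "' already selected")
  }
  avail <- sort(unique(state$remaining[[behaviour]]))
  if (!any(abs(avail - delta) < 1e-9)) {
    stop(sprintf("select_option: %g not available for '%s'; available: %s",
                 delta, behaviour, paste(avail, collapse = ", ")))
  }
  state$remaining <- state$remaining[
    abs(state$remaining[[behaviour]] - delta) < 1e-9, , drop = FALSE]
  state$choices[[behaviour]] <- delta
  state
}

#' @export
print.selection_state <- function(x, ...) {
  cat(sprintf("Selection state (band %+.1f): %d option(s) remaining\n",
              x$band, nrow(x$remaining)))
  if (length(x$choices)) {
    cat("  Chosen:", paste(sprintf("%s %+g", names(x$choices),
                                   unlist(x$choices)), collapse = ", "), "\n")
  }
  invisible(x)
}
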