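#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis in one validated
#' object. \code{read_pipeline_config} reads the same settings from a YAML
#' file; unknown keys are rejected so typos cannot silently fall back to
#' defaults.
#'
#' @param input_csv path to a person-level cohort CSV (raw items); when
#'   \code{NULL} a synthetic cohort is simulated from \code{cohort}.
#' @param cohort a \code{\link{cohort_config}} for simulation.
#' @param seed integer seed for the run (overrides \code{cohort$seed}).
#' @param cap zero-replacement cap, minutes.
#' @param lambda fixed BoxCox exponent, or \code{NULL} to estimate.
#' @param step,radius time-grid settings, minutes.
#' @param targets band centres, PedsQL points.
#' @param tolerance band half-width, PedsQL points.
#' @param summary_bands bands to export per-behaviour summaries for.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input_csv = NULL, cohort = cohort_config(),
                            seed = 1L, cap = 10, lambda = NULL, step = 10,
                            radius = 30,
                            targets = c(-rev(seq(0.5, 2.5, 0.5)),
                                        seq(0.5, 2.5, 0.5)),
                            tolerance = 0.25,
                            summary_bands = c(2, 2.5)) {
  if (cap <= 0) stop("pipeline_config: cap must be positive")
  if (tolerance <= 0) stop("pipeline_config: tolerance must be positive")
  if (!all(summary_bands %in% targets)) {
    stop("pipeline_config: summary_bands must be a subset of targets")
  }
  out <- list(input_csv = input_csv, cohort = cohort, seed = as.integer(seed),
              cap = cap, lambda = lambda, step = step, radius = radius,
              targets = targets, tolerance = tolerance,
              summary_bands = summary_bands)
  class(out) <- "pipeline_config"
  out
}

#' @rdname pipeline_config
#' @param path YAML file with any subset of the scalar/vector settings above
#'   (plus an optional \code{cohort:} block of \code{\link{cohort_config}}
#'   arguments).
#' @export
read_pipeline_config <- function(path) {
  # keep YAML-1.1 boolean literals (y/n/yes/no) verbatim: `n:` is the cohort
  # size key, not a boolean
  raw <- yaml::read_yaml(path, handlers = list(
    "bool#no" = function(x) x, "bool#yes" = function(x) x))
  allowed <- setdiff(names(formals(pipeline_config)), "cohort")
  allowed <- c(allowed, "cohort")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("read_pipeline_config: unknown key(s): ",
         paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$cohort)) {
    cohort_allowed <- names(formals(cohort_config))
    unknown_c <- setdiff(names(raw$cohort), cohort_allowed)
    if (length(unknown_c)) {
      stop("read_pipeline_config: unknown cohort key(s): ",
           paste(unknown_c, collapse = ", "))
    }
    raw$cohort <- do.call(cohort_config, raw$cohort)
  }
  do.call(pipeline_config, raw)
}

cohort_columns <- function() {
  c(time_parts(), unlist(diet_items(), use.names = FALSE), pedsql_items(),
    covariate_names())
}

#' Read and validate a person-level cohort CSV
#'
#' Comma-separated, UTF-8, mandatory header, empty cell = missing. Columns:
#' the seven durations (min/day), nine diet items (0-3), eight PedsQL items
#' (0-4) and the covariates \code{age}, \code{sex} (0/1), \code{sep}.
#' Schema violations are reported with the offending row and column.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  miss <- setdiff(cohort_columns(), names(d))
  if (length(miss)) {
    stop("read_cohort: missing column(s): ", paste(miss, collapse = ", "))
  }
  validate_cohort(d)
  d
}

#' @rdname read_cohort
#' @param data cohort data.frame to validate in place.
#' @export
validate_cohort <- function(data) {
  check_range <- function(cols, lo, hi, what, integer_only = TRUE) {
    m <- as_part_matrix(data, cols, "validate_cohort")
    bad <- !is.na(m) & (m < lo | m > hi |
                          (integer_only & m != floor(m)))
    if (any(bad)) {
      w <- first_bad(bad)
      stop(sprintf(
        "validate_cohort: %s value %s at row %d, column '%s' (allowed %g-%g)",
        what, format(m[w$row, w$col]), w$row, colnames(m)[w$col], lo, hi))
    }
  }
  check_range(unlist(diet_items(), use.names = FALSE), 0, 3, "diet item")
  check_range(pedsql_items(), 0, 4, "PedsQL item")
  check_range("sex", 0, 1, "sex")
  tm <- as_part_matrix(data, time_parts(), "validate_cohort")
  bad_neg <- !is.na(tm) & tm < 0
  if (any(bad_neg)) {
    w <- first_bad(bad_neg)
    stop(sprintf("validate_cohort: negative duration at row %d, column '%s'",
                 w$row, colnames(tm)[w$col]))
  }
  sums <- rowSums(tm)
  bad_sum <- !is.na(sums) & abs(sums - DAY_MIN) > 0.5
  if (any(bad_sum)) {
    i <- which(bad_sum)[1]
    stop(sprintf("validate_cohort: durations at row %d sum to %.1f, not 1440",
                 i, sums[i]))
  }
  invisible(TRUE)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(data, path) {
  utils::write.csv(data[, cohort_columns(), drop = FALSE], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Serialise / restore a fitted model
#'
#' Writes the fields needed to run the equivalence engine without refitting
#' (BoxCox parameters, coefficients, basis, sample SDs, covariate fixing
#' values) to a JSON text artifact; \code{read_pf_model} restores a reduced
#' \code{pf_model} object usable with \code{\link{predict_difference}} and
#' \code{\link{enumerate_options}} (but without the underlying \code{lm},
#' so refit for inference).
#'
#' @param object a \code{\link{pf_model}} fit.
#' @param path JSON path.
#' @export
write_pf_model <- function(object, path) {
  stopifnot(inherits(object, "pf_model"))
  payload <- list(
    lambda = object$lambda, shift = object$shift, coef = as.list(object$coef),
    sigma2 = object$sigma2, n = object$n, df_residual = object$df_residual,
    cap = object$cap, sds = as.list(object$sds),
    covariate_fix = as.list(object$covariate_fix),
    sbp = unclass(as.data.frame(object$sbp)),
    sbp_parts = colnames(object$sbp)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pf_model
#' @export
read_pf_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sbp <- as.matrix(as.data.frame(p$sbp))[, p$sbp_parts, drop = FALSE]
  rownames(sbp) <- paste0("z", seq_len(nrow(sbp)))
  out <- list(
    lm = NULL,
    coef = unlist(p$coef), lambda = p$lambda, shift = p$shift,
    sigma2 = p$sigma2, n = p$n, df_residual = p$df_residual, cap = p$cap,
    sbp = sbp, sds = unlist(p$sds), covariate_fix = unlist(p$covariate_fix),
    data = NULL, n_dropped = NA_integer_
  )
  class(out) <- "pf_model"
  out
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) simulate, then score, preprocess, fit, enumerate
#' and summarise, writing every artifact to \code{out_dir}: the cohort CSV
#' (when simulated), the scored analytic CSV, the model JSON, the banded
#' option table CSV, per-band summary CSVs, and a run log recording the
#' settings in effect and the sample size after each complete-case
#' filtering step (valid time use, complete diet, complete physical
#' functioning, complete covariates). Outputs contain no timestamps, so a
#' rerun with the same config and seed is byte-identical.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the fitted model, reference profile,
#'   option table, summaries, attrition counts and artifact paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  log_lines <- c("equiv24 pipeline run", sprintf("seed: %d", config$seed))

  if (is.null(config$input_csv)) {
    cohort_cfg <- config$cohort
    cohort_cfg$seed <- config$seed
    cohort <- simulate_cohort(cohort_cfg)
    raw <- cohort$data
    paths$cohort_csv <- file.path(out_dir, "cohort.csv")
    write_cohort(raw, paths$cohort_csv)
    log_lines <- c(log_lines, sprintf("simulated cohort: n = %d", nrow(raw)))
  } else {
    raw <- read_cohort(config$input_csv)
    log_lines <- c(log_lines, sprintf("input: %s (n = %d)", config$input_csv,
                                      nrow(raw)))
  }
  validate_cohort(raw)

  # complete-case attrition, mirroring the filtering order of the study flow
  n0 <- nrow(raw)
  tm <- as_part_matrix(raw, time_parts(), "run_pipeline")
  ok_time <- stats::complete.cases(tm) & abs(rowSums(tm) - DAY_MIN) <= 0.5
  d1 <- raw[ok_time, , drop = FALSE]
  scored <- score_cohort(d1)
  ok_diet <- stats::complete.cases(scored[, diet_scores()])
  d2 <- scored[ok_diet, , drop = FALSE]
  ok_pf <- !is.na(d2$pf)
  d3 <- d2[ok_pf, , drop = FALSE]
  ok_cov <- stats::complete.cases(d3[, covariate_names()])
  d4 <- d3[ok_cov, , drop = FALSE]
  attrition <- c(input = n0, valid_time_use = nrow(d1),
                 complete_diet = nrow(d2), complete_pf = nrow(d3),
                 complete_covariates = nrow(d4))
  log_lines <- c(log_lines, "attrition:",
                 sprintf("  %s: %d", names(attrition), attrition))

  paths$analytic_csv <- file.path(out_dir, "analytic.csv")
  utils::write.csv(d4, paths$analytic_csv, row.names = FALSE, na = "")

  fit <- pf_model(d4, lambda = config$lambda, cap = config$cap)
  paths$model_json <- file.path(out_dir, "model.json")
  write_pf_model(fit, paths$model_json)
  log_lines <- c(log_lines,
                 sprintf("model: n = %d, lambda = %.6f, shift = %g, sigma2 = %.6g",
                         fit$n, fit$lambda, fit$shift, fit$sigma2),
                 sprintf("settings: cap = %g min, step = %g min, radius = %g min, tolerance = %g",
                         config$cap, config$step, config$radius,
                         config$tolerance))

  time_pos <- replace_zeros(as_part_matrix(d4, time_parts(), "run_pipeline"),
                            cap = config$cap)
  ref <- reference_profile(time_pos, d4[, diet_scores()], step = config$step)
  log_lines <- c(log_lines, "reference profile:",
                 sprintf("  %s: %g", names(ref$time), ref$time),
                 sprintf("  %s: %g", names(ref$diet), ref$diet))

  tab <- enumerate_options(fit, ref, step = config$step,
                           radius = config$radius, targets = config$targets,
                           tolerance = config$tolerance,
                           keep_bands = config$summary_bands)
  paths$options_csv <- file.path(out_dir, "options.csv")
  utils::write.csv(tab$options, paths$options_csv, row.names = FALSE)
  log_lines <- c(log_lines, "option bands:",
                 sprintf("  %s: %d", names(tab$counts), tab$counts))

  summaries <- list()
  for (b in config$summary_bands) {
    s <- summarize_options(tab, b)
    key <- sprintf("summary_band_%+0.1f", b)
    p <- file.path(out_dir, paste0(gsub("[+]", "plus", gsub("-", "minus", key)),
                                   ".csv"))
    utils::write.csv(as.data.frame(s), p, row.names = FALSE)
    summaries[[as.character(b)]] <- s
    paths[[key]] <- p
  }

  paths$run_log <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, paths$run_log)

  invisible(list(fit = fit, reference = ref, options = tab,
                 summaries = summaries, attrition = attrition,
                 paths = paths))
}
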