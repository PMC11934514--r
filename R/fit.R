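#' Fit the BoxCox linear model of physical functioning on time use and diet
#'
#' The analysis model: physical functioning (PedsQL 0-100), BoxCox
#' transformed to normalise residuals, regressed by ordinary least squares on
#' the six ilr coordinates of the 24-h time-use composition, the three diet
#' serving scores, and the covariates age, sex and socioeconomic position.
#'
#' Preprocessing is part of the fit: records with any missing analysis
#' variable are dropped (complete-case), compositional zeros are replaced
#' (\code{\link{replace_zeros}}, cap \code{cap} minutes), and compositions
#' are expressed in ilr coordinates under \code{sbp}. Because all valid
#' orthonormal bases span the same column space, fitted values, predictions
#' and the compositional block F-test do not depend on the basis choice.
#'
#' When the outcome can be exactly zero a unit shift is applied before the
#' BoxCox transform (\code{shift = 1} if \code{min(y) == 0}, else 0); the
#' shift is recorded and undone on back-transformation. \code{lambda} is
#' estimated by profile likelihood over \code{[-5, 5]} unless supplied.
#'
#' @param data data.frame with the seven duration columns (min/day, rows
#'   summing to 1440), \code{fruit_veg}, \code{discretionary}, \code{ssb},
#'   \code{age}, \code{sex} (0/1, 1 = female), \code{sep}, and the outcome
#'   column \code{pf}.
#' @param lambda BoxCox exponent; \code{NULL} (default) to estimate.
#' @param sbp ilr basis from \code{\link{make_sbp}}; default pivot basis in
#'   the canonical part order.
#' @param cap zero-replacement cap, minutes.
#' @param shift additive offset applied to the outcome before the BoxCox
#'   transform; \code{NULL} for the automatic rule above.
#' @return an object of class \code{pf_model}; see Details. Components
#'   include \code{lm} (the underlying \code{\link[stats]{lm}} fit on the
#'   transformed scale), \code{lambda}, \code{shift}, \code{coef},
#'   \code{sigma2}, \code{sbp}, \code{n}, \code{df_residual}, \code{sds}
#'   (analytic-sample SDs used for standardised coefficients) and
#'   \code{covariate_fix} (mean age and SEP, modal sex) used when holding
#'   covariates constant.
#' @seealso \code{\link{composition_ftest}}, \code{\link{standardized_betas}},
#'   \code{\link{sex_interaction_screen}}, \code{\link{enumerate_options}}
#' @export
pf_model <- function(data, lambda = NULL, sbp = NULL, cap = 10,
                     shift = NULL) {
  parts <- time_parts()
  vars <- c(parts, diet_scores(), covariate_names(), "pf")
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    stop("pf_model: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(sbp)) sbp <- make_sbp(parts)

  cc <- stats::complete.cases(data[, vars])
  d <- data[cc, vars, drop = FALSE]
  n <- nrow(d)
  p <- nrow(sbp) + length(diet_scores()) + length(covariate_names()) + 1L
  if (n < p) stop(sprintf("pf_model: %d complete cases; need at least %d", n, p))

  time_raw <- as_part_matrix(d, parts, "pf_model")
  if (any(time_raw < 0)) stop("pf_model: negative durations")
  bad_sum <- abs(rowSums(time_raw) - DAY_MIN) > 0.5
  if (any(bad_sum)) {
    stop(sprintf("pf_model: row %d durations sum to %.1f, not 1440",
                 which(bad_sum)[1], rowSums(time_raw)[which(bad_sum)[1]]))
  }
  time_pos <- replace_zeros(time_raw, cap = cap)
  z <- ilr_transform(time_pos, sbp)

  y <- d$pf
  if (any(y < 0 | y > 100)) stop("pf_model: outcome outside [0, 100]")
  if (is.null(shift)) shift <- if (min(y) == 0) 1 else 0
  ys <- y + shift
  if (any(ys <= 0)) stop("pf_model: outcome not positive after shift")

  Xfr <- data.frame(z, d[, c(diet_scores(), covariate_names())])
  if (is.null(lambda)) {
    lambda <- boxcox_lambda(ys, X = as.matrix(Xfr))
  }
  t <- boxcox_transform(ys, lambda)

  # rank check with an informative message naming the collinear columns
  Xm <- cbind(`(Intercept)` = 1, as.matrix(Xfr))
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    dropped <- colnames(Xm)[qrX$pivot[(qrX$rank + 1L):ncol(Xm)]]
    stop("pf_model: rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }

  frame <- cbind(t_pf = t, Xfr)
  fit <- stats::lm(t_pf ~ ., data = frame)
  df_res <- n - p
  if (df_res == 0L) {
    warning("pf_model: saturated fit (df_residual = 0); residual variance is zero")
  }
  sigma2 <- if (df_res > 0) sum(fit$residuals^2) / df_res else 0

  sex_tab <- table(factor(d$sex, levels = c(0, 1)))
  sex_mode <- if (sex_tab["1"] >= sex_tab["0"]) 1 else 0  # ties -> female

  out <- list(
    lm = fit,
    coef = stats::coef(fit),
    lambda = lambda,
    shift = shift,
    sigma2 = sigma2,
    n = n,
    df_residual = df_res,
    sbp = sbp,
    cap = cap,
    sds = c(vapply(Xfr, stats::sd, numeric(1)), t_pf = stats::sd(t)),
    covariate_fix = c(age = mean(d$age), sex = sex_mode, sep = mean(d$sep)),
    data = cbind(d, z),
    n_dropped = sum(!cc)
  )
  class(out) <- "pf_model"
  out
}

design_names <- function() {
  c(paste0("z", 1:6), diet_scores(), covariate_names())
}

#' @export
print.pf_model <- function(x, digits = 3, ...) {
  cat("BoxCox linear model of physical functioning on 24-h time use and diet\n")
  cat(sprintf("  n = %d complete cases (%d dropped); lambda = %.3f; shift = %g\n",
              x$n, x$n_dropped, x$lambda, x$shift))
  cat("  Coefficients (transformed scale):\n")
  print(round(x$coef, digits))
  invisible(x)
}

#' @export
summary.pf_model <- function(object, ...) {
  out <- list(
    model = object,
    lm_summary = summary(object$lm),
    block_test = composition_ftest(object),
    std_betas = standardized_betas(object)
  )
  class(out) <- "summary.pf_model"
  out
}

#' @export
print.summary.pf_model <- function(x, ...) {
  print(x$model)
  cat("\nCompositional block F-test (all 6 ilr coordinates):\n")
  print(x$block_test)
  cat("\nStandardised diet coefficients:\n")
  print(x$std_betas, digits = 3)
  invisible(x)
}

#' @export
coef.pf_model <- function(object, ...) object$coef

# assemble the design matrix (with intercept) for new person-level data
pf_design <- function(object, newdata) {
  parts <- time_parts()
  tm <- as_part_matrix(newdata, parts, "predict")
  if (any(tm == 0)) tm <- replace_zeros(tm, cap = object$cap)
  if (any(tm <= 0)) stop("predict: non-positive durations")
  z <- ilr_transform(tm, object$sbp)
  other <- as_part_matrix(newdata, c(diet_scores(), covariate_names()),
                          "predict")
  cbind(1, z, other)
}

#' Predict physical functioning for new profiles
#'
#' @param object a \code{pf_model} fit.
#' @param newdata data.frame with duration, diet-score and covariate columns;
#'   \code{NULL} for the analytic sample.
#' @param type \code{"response"} for the 0-100 scale (BoxCox inverted, shift
#'   removed) or \code{"transformed"} for the modelling scale.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pf_model <- function(object, newdata = NULL,
                             type = c("response", "transformed"), ...) {
  type <- match.arg(type)
  t_hat <- if (is.null(newdata)) {
    unname(stats::fitted(object$lm))
  } else {
    unname(drop(pf_design(object, newdata) %*% object$coef))
  }
  if (type == "transformed") return(t_hat)
  boxcox_inverse(t_hat, object$lambda) - object$shift
}

#' @export
residuals.pf_model <- function(object, type = c("transformed", "response"),
                               ...) {
  type <- match.arg(type)
  if (type == "transformed") return(unname(stats::residuals(object$lm)))
  object$data$pf - predict(object)
}

#' Simulate outcomes from a fitted model
#'
#' Draws transformed-scale outcomes from the fitted normal model at the
#' analytic sample's design points, back-transforms and clamps to
#' \code{[0, 100]}.
#'
#' @param object a \code{pf_model} fit.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data.frame with \code{nsim} columns of simulated 0-100 scores.
#' @export
simulate.pf_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- stats::fitted(object$lm)
  n <- length(mu)
  sims <- replicate(nsim, {
    t_star <- mu + stats::rnorm(n, 0, sqrt(object$sigma2))
    lo <- boxcox_transform(1e-9 + object$shift, object$lambda)
    hi <- boxcox_transform(100 + object$shift, object$lambda)
    pmin(pmax(t_star, lo), hi)
  })
  out <- as.data.frame(boxcox_inverse(sims, object$lambda) - object$shift)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.pf_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  r <- stats::residuals(x$lm)
  stats::qqnorm(r, main = "Residual normal Q-Q (transformed scale)")
  stats::qqline(r)
  graphics::plot(stats::fitted(x$lm), r, xlab = "Fitted (transformed)",
                 ylab = "Residual", main = "Residuals vs fitted")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
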