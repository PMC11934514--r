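#' Configuration for the synthetic adolescent cohort generator
#'
#' Bundles every ground-truth parameter of the generative model: a
#' logistic-normal 24-h time-use composition centred on the study
#' population's compositional mean, categorical diet questionnaire items,
#' normally distributed covariates, and a physical-functioning outcome
#' generated from a known linear model on the BoxCox scale and pushed down
#' to PedsQL item responses. With known truth, every stage of the analysis
#' (scoring, preprocessing, model fit, equivalence enumeration) can be
#' validated end to end.
#'
#' Time-use variation is parameterised by per-part log-scale SDs
#' (\code{log_sd}); the implied ilr covariance is
#' \code{V diag(log_sd^2) V'}. The true time-use effect is a log-contrast:
#' per-part coefficients \code{time_coefs} (summing to zero) on log minutes,
#' equivalent to ilr coefficients \code{V \%*\% time_coefs}. The intercept is
#' derived so the expected outcome at the mean profile equals
#' \code{mean_outcome}.
#'
#' @param n cohort size.
#' @param seed integer seed stored with the config; \code{NULL} to leave the
#'   RNG state alone.
#' @param mean_composition named 7-part compositional mean, min/day.
#' @param log_sd named per-part log-scale SDs.
#' @param ilr_covariance optional 6x6 positive (semi-)definite matrix
#'   overriding the one implied by \code{log_sd}.
#' @param zero_rates named per-part probabilities of a structural zero
#'   (sleep and self-care must be zero-free).
#' @param diet_item_probs list of 9 probability vectors over responses 0-3,
#'   named by item.
#' @param time_coefs named per-part log-contrast outcome coefficients
#'   (transformed scale), summing to 0.
#' @param beta_diet,beta_covariates named true coefficients (transformed
#'   scale).
#' @param mean_outcome expected PedsQL score at the mean profile.
#' @param true_lambda,true_shift BoxCox exponent and shift of the generative
#'   outcome model.
#' @param sigma residual SD on the transformed scale.
#' @param missing_pedsql_rate per-item missingness probability.
#' @param cap zero-replacement cap used in the generative preprocessing.
#' @return object of class \code{cohort_config}; includes the derived
#'   \code{ilr_covariance}, \code{sbp} and full \code{true_beta} vector
#'   (intercept first, then \code{z1..z6}, diet, covariates).
#' @export
cohort_config <- function(
    n = 2000,
    seed = NULL,
    mean_composition = c(sleep = 741, self_care = 125, screen = 163,
                         quiet = 175, physical_activity = 50, school = 129,
                         domestic_social = 58),
    log_sd = c(sleep = 0.11, self_care = 0.50, screen = 0.85, quiet = 0.65,
               physical_activity = 1.20, school = 1.15,
               domestic_social = 1.20),
    ilr_covariance = NULL,
    zero_rates = c(sleep = 0, self_care = 0, screen = 0.01, quiet = 0.01,
                   physical_activity = 0.03, school = 0.01,
                   domestic_social = 0.02),
    diet_item_probs = NULL,
    time_coefs = c(sleep = 180, self_care = -90, screen = -100, quiet = -90,
                   physical_activity = 150, school = -20,
                   domestic_social = -30),
    beta_diet = c(fruit_veg = 20, discretionary = -20, ssb = -29),
    beta_covariates = c(age = -20, sex = -40, sep = 15),
    mean_outcome = 89,
    true_lambda = 2,
    true_shift = 0,
    sigma = 450,
    missing_pedsql_rate = 0.01,
    cap = 10) {
  parts <- time_parts()
  if (n < 1) stop("cohort_config: n must be at least 1")
  mean_composition <- mean_composition[parts]
  log_sd <- log_sd[parts]
  zero_rates <- zero_rates[parts]
  if (any(is.na(mean_composition)) || any(mean_composition <= 0)) {
    stop("cohort_config: mean_composition must be positive for all 7 parts")
  }
  if (any(zero_rates < 0 | zero_rates > 1)) {
    stop("cohort_config: zero_rates must be probabilities")
  }
  if (any(zero_rates[c("sleep", "self_care")] > 0)) {
    stop("cohort_config: sleep and self-care are zero-free behaviours")
  }
  if (abs(sum(time_coefs[parts])) > 1e-8) {
    stop("cohort_config: time_coefs must sum to 0 (log-contrast)")
  }
  if (sigma < 0) stop("cohort_config: sigma must be non-negative")

  if (is.null(diet_item_probs)) {
    fv <- c(0.36, 0.25, 0.19, 0.20)       # item mean 1.23 -> score mean 3.69
    disc <- c(0.65, 0.25, 0.05, 0.05)     # item mean 0.50 -> score mean 2.0
    ssb <- c(0.78, 0.16, 0.04, 0.02)      # item mean 0.30 -> score mean 0.6
    items <- diet_items()
    diet_item_probs <- c(
      stats::setNames(rep(list(fv), 3), items$fruit_veg),
      stats::setNames(rep(list(disc), 4), items$discretionary),
      stats::setNames(rep(list(ssb), 2), items$ssb)
    )
  }
  for (nm in names(diet_item_probs)) {
    p <- diet_item_probs[[nm]]
    if (length(p) != 4 || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("cohort_config: diet_item_probs[['", nm,
           "']] must be 4 non-negative probabilities summing to 1")
    }
  }

  sbp <- make_sbp(parts)
  if (is.null(ilr_covariance)) {
    ilr_covariance <- sbp %*% diag(log_sd^2) %*% t(sbp)
  }
  ev <- eigen(ilr_covariance, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) {
    stop("cohort_config: ilr_covariance is not positive semi-definite")
  }

  beta_z <- drop(sbp %*% time_coefs[parts])
  names(beta_z) <- paste0("z", 1:6)
  z_mean <- drop(ilr_transform(mean_composition, sbp))
  e_item <- vapply(diet_item_probs, function(p) sum(p * 0:3), numeric(1))
  grp <- diet_items()
  e_diet <- c(fruit_veg = sum(e_item[grp$fruit_veg]),
              discretionary = sum(e_item[grp$discretionary]),
              ssb = sum(e_item[grp$ssb]))
  e_cov <- c(age = 14.4, sex = 0.5, sep = 0)
  t_target <- boxcox_transform(mean_outcome + true_shift, true_lambda)
  intercept <- t_target - sum(z_mean * beta_z) -
    sum(e_diet * beta_diet[diet_scores()]) -
    sum(e_cov * beta_covariates[covariate_names()])

  cfg <- list(
    n = n, seed = seed,
    mean_composition = mean_composition, log_sd = log_sd,
    ilr_covariance = ilr_covariance, zero_rates = zero_rates,
    diet_item_probs = diet_item_probs,
    time_coefs = time_coefs[parts],
    beta_diet = beta_diet[diet_scores()],
    beta_covariates = beta_covariates[covariate_names()],
    mean_outcome = mean_outcome,
    true_lambda = true_lambda, true_shift = true_shift, sigma = sigma,
    missing_pedsql_rate = missing_pedsql_rate, cap = cap, sbp = sbp,
    true_beta = c("(Intercept)" = unname(intercept), beta_z,
                  beta_diet[diet_scores()],
                  beta_covariates[covariate_names()]),
    expected_diet = e_diet
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: n = %d, lambda = %g, sigma = %g\n",
              x$n, x$true_lambda, x$sigma))
  cat("  Mean composition (min/day):\n")
  print(x$mean_composition)
  cat("  True coefficients (transformed scale):\n")
  print(round(x$true_beta, 2))
  invisible(x)
}

#' Generate covariates
#'
#' Age ~ Normal(14.4, 0.5) years, sex ~ Bernoulli(0.5) (1 = female),
#' socioeconomic position ~ Normal(0, 1) z-score.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param n number of persons; defaults to \code{config$n}.
#' @return data.frame with columns \code{age}, \code{sex}, \code{sep}.
#' @export
gen_covariates <- function(config, n = config$n) {
  data.frame(
    age = stats::rnorm(n, 14.4, 0.5),
    sex = stats::rbinom(n, 1, 0.5),
    sep = stats::rnorm(n, 0, 1)
  )
}

#' Generate 24-h time-use compositions
#'
#' Draws ilr coordinates from a multivariate normal centred on the ilr image
#' of the configured compositional mean, inverts to min/day compositions,
#' rounds to whole minutes (largest-remainder, preserving the 1440 total)
#' and injects structural zeros: with probability \code{zero_rates[b]} a
#' person's minutes in behaviour \code{b} are transferred to their largest
#' remaining behaviour, mimicking "did none of this on the diary day".
#'
#' @param config a \code{\link{cohort_config}}.
#' @param n number of persons.
#' @return integer-valued matrix (n x 7) of durations summing to 1440 per
#'   row, with zeros where injected.
#' @export
gen_timeuse <- function(config, n = config$n) {
  parts <- time_parts()
  Sigma <- config$ilr_covariance
  es <- eigen(Sigma, symmetric = TRUE)
  if (any(es$values < -1e-8)) {
    stop("gen_timeuse: ilr_covariance is not positive semi-definite")
  }
  A <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), nrow(Sigma))
  mu <- drop(ilr_transform(config$mean_composition, config$sbp))
  Z <- matrix(stats::rnorm(n * length(mu)), n) %*% t(A)
  Z <- sweep(Z, 2, mu, "+")
  X <- ilr_inverse(Z, config$sbp, total = DAY_MIN)
  X <- t(apply(X, 1, largest_remainder_round, step = 1, total = DAY_MIN))
  colnames(X) <- parts
  for (b in parts) {
    r <- config$zero_rates[[b]]
    if (r > 0) {
      hit <- which(stats::runif(n) < r)
      for (i in hit) {
        minutes <- X[i, b]
        X[i, b] <- 0
        donee <- names(which.max(X[i, setdiff(parts, b)]))
        X[i, donee] <- X[i, donee] + minutes
      }
    }
  }
  X
}

#' Generate diet questionnaire item responses
#'
#' Independent categorical draws per item from the configured response
#' probabilities over \code{0:3}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param n number of persons.
#' @return data.frame with the nine item columns.
#' @export
gen_diet <- function(config, n = config$n) {
  out <- lapply(config$diet_item_probs, function(p) {
    sample(0:3, n, replace = TRUE, prob = p)
  })
  as.data.frame(out)
}

#' Generate PedsQL item responses from the true outcome model
#'
#' The latent transformed score is \code{t = X beta_true + N(0, sigma^2)},
#' where the design row is built with the same preprocessing the analysis
#' uses (zero replacement, ilr under the configured basis, diet serving
#' scores). \code{t} is back-transformed through the true BoxCox
#' parameters, clamped to [0, 100], and converted to eight item responses
#' whose mean reproduces the score at the nearest achievable grid point
#' (the item grid resolves 25/8 = 3.125 score points). Item-level
#' missingness is then applied at the configured rate.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param durations duration matrix from \code{\link{gen_timeuse}}.
#' @param diet item data.frame from \code{\link{gen_diet}}.
#' @param covariates data.frame from \code{\link{gen_covariates}}.
#' @return data.frame with columns \code{pf_1}..\code{pf_8}.
#' @export
gen_outcome <- function(config, durations, diet, covariates) {
  if (config$sigma < 0) stop("gen_outcome: sigma must be non-negative")
  n <- nrow(durations)
  time_pos <- replace_zeros(durations, cap = config$cap)
  z <- ilr_transform(time_pos, config$sbp)
  scores <- score_diet(diet)
  X <- cbind(1, z, as.matrix(scores[, diet_scores()]),
             as.matrix(covariates[, covariate_names()]))
  t <- drop(X %*% config$true_beta) +
    stats::rnorm(n, 0, config$sigma)
  t <- pmax(t, boxcox_transform(1e-6, config$true_lambda))
  y <- boxcox_inverse(t, config$true_lambda) - config$true_shift
  y <- pmin(pmax(y, 0), 100)

  total <- round_half_away(8 * (4 - y / 25))   # 0..32 response units
  total <- pmin(pmax(total, 0), 32)
  base <- total %/% 8
  extra <- total %% 8
  items <- matrix(base, n, 8)
  bump <- outer(extra, 1:8, ">=")
  items[bump] <- items[bump] + 1
  if (config$missing_pedsql_rate > 0) {
    miss <- matrix(stats::runif(n * 8) < config$missing_pedsql_rate, n, 8)
    items[miss] <- NA_integer_
  }
  items <- as.data.frame(items)
  names(items) <- pedsql_items()
  items
}

#' Simulate a full synthetic cohort
#'
#' Runs the four generators in a fixed order (covariates, time use, diet,
#' outcome) under the configured seed, so identical configs give identical
#' cohorts.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return object of class \code{synthetic_cohort}: list with \code{data}
#'   (person-level data.frame: 7 duration columns, 9 diet items, 8 PedsQL
#'   items, 3 covariates) and the generating \code{config}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  covars <- gen_covariates(config)
  durations <- gen_timeuse(config)
  diet <- gen_diet(config)
  pf_items <- gen_outcome(config, durations, diet, covars)
  out <- list(
    data = cbind(as.data.frame(durations), diet, pf_items, covars),
    config = config
  )
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d persons, %d variables\n",
              nrow(x$data), ncol(x$data)))
  invisible(x)
}
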