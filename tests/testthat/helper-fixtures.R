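# Fixtures built in code: toy models, small cohorts, printed study values.

# printed compositional mean and reference profile of the emulated study
study_comp_mean <- c(sleep = 741, self_care = 125, screen = 163,
                      quiet = 175, physical_activity = 50, school = 129,
                      domestic_social = 58)
study_reference_time <- c(sleep = 740, self_care = 130, screen = 160,
                         quiet = 170, physical_activity = 50, school = 130,
                         domestic_social = 60)
study_diet_means <- c(fruit_veg = 3.7, discretionary = 2.0, ssb = 0.6)
study_reference_diet <- c(fruit_veg = 4, discretionary = 2, ssb = 1)

study_reference <- function() {
  reference_profile(study_comp_mean, study_diet_means)
}

# hand-built pf_model-like object: all coefficients zero except those given
toy_model <- function(coef = numeric(0), lambda = 1, shift = 0,
                      covariate_fix = c(age = 14.4, sex = 1, sep = 0)) {
  nm <- c("(Intercept)", paste0("z", 1:6), "fruit_veg", "discretionary",
          "ssb", "age", "sex", "sep")
  cf <- stats::setNames(rep(0, length(nm)), nm)
  cf[names(coef)] <- coef
  obj <- list(coef = cf, lambda = lambda, shift = shift, sbp = make_sbp(),
              cap = 10, covariate_fix = covariate_fix, sigma2 = 1,
              n = 100L, df_residual = 87L,
              sds = stats::setNames(rep(1, 13), c(nm[-1], "t_pf")))
  class(obj) <- "pf_model"
  obj
}

# small scored analytic data.frame with a known linear outcome (lambda = 1)
make_toy_cohort <- function(n = 120, beta = NULL, sigma = 1, seed = 99) {
  set.seed(seed)
  cfg <- cohort_config(n = n, sigma = 1)
  tm <- gen_timeuse(cfg, n)
  z <- ilr_transform(replace_zeros(tm), make_sbp())
  d <- data.frame(tm, z)
  d$fruit_veg <- sample(0:9, n, TRUE)
  d$discretionary <- sample(0:12, n, TRUE)
  d$ssb <- sample(0:6, n, TRUE)
  d$age <- rnorm(n, 14.4, 0.5)
  d$sex <- rbinom(n, 1, 0.5)
  d$sep <- rnorm(n)
  if (is.null(beta)) {
    beta <- c("(Intercept)" = 70, z1 = 2, z2 = -1, z3 = 0.5, z4 = 0,
              z5 = 1.5, z6 = -0.5, fruit_veg = 0.4, discretionary = -0.3,
              ssb = -0.5, age = -0.5, sex = -1, sep = 0.5)
  }
  X <- cbind(1, as.matrix(d[, names(beta)[-1]]))
  d$pf <- pmin(pmax(drop(X %*% beta) + rnorm(n, 0, sigma), 0), 100)
  attr(d, "beta") <- beta
  d
}

# independent banding rule used by oracles (targets +/-0.5..2.5, tol 0.25)
oracle_band <- function(d, targets = c(-rev(seq(0.5, 2.5, 0.5)),
                                       seq(0.5, 2.5, 0.5)),
                        tolerance = 0.25) {
  out <- rep(NA_real_, length(d))
  for (t in targets) out[abs(d - t) < tolerance] <- t
  out
}
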