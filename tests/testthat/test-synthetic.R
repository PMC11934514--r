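test_that("identical config and seed give identical cohorts", {
  cfg <- cohort_config(n = 200, seed = 101)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$data, b$data)
  cfg2 <- cohort_config(n = 200, seed = 102)
  expect_false(identical(simulate_cohort(cfg2)$data, a$data))
})

test_that("generated cohorts pass the upstream validators unchanged", {
  co <- simulate_cohort(cohort_config(n = 300, seed = 103))
  expect_true(validate_cohort(co$data))
  sc <- score_cohort(co$data)
  expect_true(all(sc$fruit_veg >= 0 & sc$fruit_veg <= 9, na.rm = TRUE))
  expect_true(all(sc$ssb >= 0 & sc$ssb <= 6, na.rm = TRUE))
  expect_true(all(sc$pf >= 0 & sc$pf <= 100, na.rm = TRUE))
})

test_that("time-use generator rows close to 1440 and honour zero settings", {
  cfg <- cohort_config(n = 400, seed = 104)
  set.seed(104)
  tm <- gen_timeuse(cfg)
  expect_true(all(rowSums(tm) == 1440))
  expect_true(all(tm[, c("sleep", "self_care")] > 0))

  cfg0 <- cohort_config(n = 200, seed = 105,
                        zero_rates = stats::setNames(rep(0, 7), time_parts()))
  set.seed(105)
  tm0 <- gen_timeuse(cfg0)
  expect_true(all(tm0 > 0))

  # degenerate covariance: every row is the rounded mean composition
  cfgd <- cohort_config(n = 20, seed = 106,
                        ilr_covariance = matrix(0, 6, 6),
                        zero_rates = stats::setNames(rep(0, 7), time_parts()))
  set.seed(106)
  tmd <- gen_timeuse(cfgd)
  expect_equal(unname(apply(tmd, 2, stats::var)), rep(0, 7))
  expect_equal(unname(rowSums(tmd)), rep(1440, 20))
})

test_that("config validation rejects impossible settings", {
  expect_error(cohort_config(n = 0), "n must be")
  expect_error(cohort_config(zero_rates = c(
    sleep = 0.1, self_care = 0, screen = 0, quiet = 0,
    physical_activity = 0, school = 0, domestic_social = 0)), "zero-free")
  expect_error(cohort_config(ilr_covariance = diag(c(1, 1, 1, 1, 1, -1))),
               "definite")
  expect_error(cohort_config(time_coefs = c(
    sleep = 1, self_care = 0, screen = 0, quiet = 0,
    physical_activity = 0, school = 0, domestic_social = 0)), "sum to 0")
  expect_error(cohort_config(sigma = -1), "sigma")
  bad_probs <- cohort_config()$diet_item_probs
  bad_probs[["fruit"]] <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(cohort_config(diet_item_probs = bad_probs), "summing to 1")
})

test_that("diet generator respects degenerate probabilities and score ranges", {
  cfg <- cohort_config(n = 100, seed = 107)
  probs <- cfg$diet_item_probs
  for (nm in diet_items()$fruit_veg) probs[[nm]] <- c(0, 1, 0, 0)
  cfg2 <- cohort_config(n = 100, seed = 107, diet_item_probs = probs)
  set.seed(107)
  d <- gen_diet(cfg2)
  s <- score_diet(d)
  expect_true(all(s$fruit_veg == 3))
  expect_true(all(s$discretionary >= 0 & s$discretionary <= 12))
})

test_that("outcome generator round-trips scores within the item-grid resolution", {
  cfg <- cohort_config(n = 300, seed = 108, missing_pedsql_rate = 0)
  set.seed(108)
  covars <- gen_covariates(cfg)
  tm <- gen_timeuse(cfg)
  diet <- gen_diet(cfg)
  # deterministic latent score: sigma = 0
  cfg0 <- cohort_config(n = 300, seed = 108, sigma = 0,
                        missing_pedsql_rate = 0)
  pf_items <- gen_outcome(cfg0, tm, diet, covars)
  score <- score_pedsql(pf_items)
  # recompute the latent score through the same generative chain
  z <- ilr_transform(replace_zeros(tm, cap = cfg0$cap), cfg0$sbp)
  X <- cbind(1, z, as.matrix(score_diet(diet)),
             as.matrix(covars[, covariate_names()]))
  y_latent <- boxcox_inverse(drop(X %*% cfg0$true_beta), cfg0$true_lambda)
  y_latent <- pmin(pmax(y_latent, 0), 100)
  expect_true(all(abs(score - y_latent) <= 25 / 8 / 2 + 1e-9))
})

test_that("constant truth gives a constant outcome", {
  cfg <- cohort_config(n = 50, seed = 109, sigma = 0,
                       missing_pedsql_rate = 0,
                       time_coefs = stats::setNames(rep(0, 7), time_parts()),
                       beta_diet = c(fruit_veg = 0, discretionary = 0,
                                     ssb = 0),
                       beta_covariates = c(age = 0, sex = 0, sep = 0))
  co <- simulate_cohort(cfg)
  sc <- score_cohort(co$data)
  # every person's score equals the back-transformed intercept, up to the
  # item grid
  y0 <- boxcox_inverse(cfg$true_beta[["(Intercept)"]], cfg$true_lambda)
  expect_true(all(abs(sc$pf - y0) <= 25 / 8 / 2 + 1e-9))
  expect_lt(stats::sd(sc$pf), 1e-12)
})

test_that("covariate generator hits its moments and is reproducible", {
  cfg <- cohort_config(n = 5000, seed = 110)
  set.seed(110)
  cv <- gen_covariates(cfg)
  expect_lt(abs(mean(cv$age) - 14.4), 3 * 0.5 / sqrt(5000))
  expect_lt(abs(mean(cv$sex) - 0.5), 3 * 0.5 / sqrt(5000))
  expect_lt(abs(mean(cv$sep) - 0), 3 / sqrt(5000))
  set.seed(110)
  expect_identical(gen_covariates(cfg), cv)
  set.seed(111)
  expect_equal(nrow(gen_covariates(cfg, n = 1)), 1L)
})

test_that("shipped defaults emulate the target population's summary statistics", {
  cfg <- cohort_config(n = 5000, seed = 112)
  co <- simulate_cohort(cfg)
  sc <- score_cohort(co$data)
  tm <- as.matrix(co$data[, time_parts()])

  # compositional mean of the clean (zero-free) draws: within 5 min per part
  zf <- tm[rowSums(tm == 0) == 0, ]
  cm <- compositional_mean(zf)
  expect_true(all(abs(cm - cfg$mean_composition) < 5))

  # diet serving-score means within 0.15 serves of the emulated population
  expect_lt(abs(mean(sc$fruit_veg) - 3.7), 0.15)
  expect_lt(abs(mean(sc$discretionary) - 2.0), 0.15)
  expect_lt(abs(mean(sc$ssb) - 0.6), 0.15)

  # physical functioning mean near the emulated population's 89.3
  expect_lt(abs(mean(sc$pf, na.rm = TRUE) - 89.3), 2)

  # arithmetic duration spreads: within +/-30% of the emulated values for
  # the six non-dominant parts; sleep absorbs the others' closure variance
  # under the independence choice, so only a loose factor-2 bound holds
  target_sd <- c(sleep = 82, self_care = 59, screen = 169, quiet = 116,
                 physical_activity = 100, school = 192,
                 domestic_social = 109)
  got_sd <- apply(tm, 2, stats::sd)
  ratio <- got_sd / target_sd
  non_dominant <- setdiff(time_parts(), "sleep")
  expect_true(all(ratio[non_dominant] > 0.7 & ratio[non_dominant] < 1.3))
  expect_lt(ratio[["sleep"]], 2)

  # zeros appear in exactly the five behaviours that allow them
  expect_true(all(colSums(tm == 0)[c("sleep", "self_care")] == 0))
  expect_true(all(colSums(tm == 0)[cfg$zero_rates > 0] > 0))
})
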