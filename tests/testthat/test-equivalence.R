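test_that("time grid handles tiny systems exactly", {
  g2 <- make_time_grid(step = 10, radius = 10, parts = c("a", "b"))
  expect_equal(unname(g2), rbind(c(-10, 10), c(0, 0), c(10, -10)))
  g0 <- make_time_grid(step = 10, radius = 0)
  expect_equal(nrow(g0), 1L)
  expect_true(all(g0 == 0))
  expect_error(make_time_grid(step = 10, radius = 25), "multiple")
})

test_that("time grid equals brute-force zero-sum enumeration for small systems", {
  for (D in 3:5) {
    radius <- 20
    levels <- seq(-radius, radius, 10)
    brute <- as.matrix(expand.grid(rep(list(levels), D)))
    brute <- brute[rowSums(brute) == 0, , drop = FALSE]
    brute <- brute[do.call(order, as.data.frame(brute)), , drop = FALSE]
    g <- make_time_grid(step = 10, radius = radius, parts = letters[1:D])
    expect_equal(unname(g), unname(brute))
  }
})

test_that("time grid drops reallocations that exhaust a behaviour", {
  ref <- reference_profile(
    c(sleep = 760, self_care = 130, screen = 160, quiet = 170,
      physical_activity = 20, school = 140, domestic_social = 60),
    c(4, 2, 1))
  g <- make_time_grid(ref, step = 10, radius = 30)
  # PA starts at 20 min: deltas of -20 and -30 would leave <= 0 minutes
  expect_true(all(g[, "physical_activity"] > -20))
  full <- make_time_grid(step = 10, radius = 30)
  expect_lt(nrow(g), nrow(full))
})

test_that("diet grid respects score bounds from the reference", {
  ref <- study_reference()
  g <- make_diet_grid(ref)
  expect_equal(nrow(g), 7 * 7 * 6)   # ssb loses -1.5 at reference 1 serve
  expect_true(all(ref$diet["ssb"] + g[, "ssb"] >= 0))
  expect_equal(sort(unique(g[, "ssb"])), seq(-1, 1.5, 0.5))
  expect_true(any(rowSums(abs(g)) == 0))  # the all-zero change is present

  ref0 <- reference_profile(study_comp_mean,
                            c(fruit_veg = 4, discretionary = 2, ssb = 0))
  g0 <- make_diet_grid(ref0)
  expect_equal(sort(unique(g0[, "ssb"])), seq(0, 1.5, 0.5))
  expect_equal(nrow(g0), 7 * 7 * 4)

  ref_hi <- reference_profile(study_comp_mean,
                              c(fruit_veg = 8.6, discretionary = 2, ssb = 1))
  g_hi <- make_diet_grid(ref_hi)   # fruit_veg reference 9 = score maximum
  expect_true(all(ref_hi$diet["fruit_veg"] + g_hi[, "fruit_veg"] <= 9))
})

test_that("predicted difference is zero at the null change and additive on the transformed scale", {
  m <- toy_model(c("(Intercept)" = 50, z5 = 3, fruit_veg = 0.5, ssb = -1),
                 lambda = 1.7)
  ref <- study_reference()
  zero <- predict_difference(m, ref, rep(0, 7), rep(0, 3))
  expect_identical(zero, 0)
  td <- c(sleep = -10, self_care = 0, screen = -10, quiet = 0,
          physical_activity = 30, school = -10, domestic_social = 0)
  dd <- c(fruit_veg = 1, discretionary = 0, ssb = -1)
  # additivity holds exactly on the transformed scale (not after inversion)
  d_time <- predict_difference(m, ref, td, rep(0, 3))
  d_diet <- predict_difference(m, ref, rep(0, 7), dd)
  d_both <- predict_difference(m, ref, td, dd)
  inv <- function(t) boxcox_inverse(t, m$lambda)
  # recover transformed contributions from back-transformed differences
  t0 <- equiv24:::pf_linpred(m, ref$time, ref$diet, m$covariate_fix)
  tt <- function(d) boxcox_transform(inv(t0) + d, m$lambda) - t0
  expect_equal(tt(d_time) + tt(d_diet), tt(d_both), tolerance = 1e-10)
  expect_error(predict_difference(m, ref, c(-40, rep(0, 6)), rep(0, 3)),
               "sum to 0")
})

test_that("a single nonzero diet coefficient gives hand-checkable differences", {
  m <- toy_model(c("(Intercept)" = 60, ssb = -2), lambda = 1)
  ref <- study_reference()
  for (delta in c(-1, -0.5, 0.5, 1.5)) {
    d <- predict_difference(m, ref, rep(0, 7),
                            c(fruit_veg = 0, discretionary = 0, ssb = delta))
    expect_equal(d, -2 * delta, tolerance = 1e-12)
  }
  expect_error(
    predict_difference(m, ref, c(-60, 60, 0, 0, 0, 0, 0) * 1,
                       rep(0, 3)),
    NA)  # feasible: self-care 130 + 60 and sleep 740 - 60 stay positive
  expect_error(
    predict_difference(m, ref, c(0, 0, 0, 0, -50, 50, 0), rep(0, 3)),
    "non-positive")
})

test_that("enumeration extracts exactly the combinations that hit a target", {
  # radius 0: only diet varies; diff = fv + ssb + 0.3 * disc, so 3.45 is
  # attainable only at the single extreme corner (+1.5, +1.5, +1.5)
  m <- toy_model(c("(Intercept)" = 60, fruit_veg = 1, discretionary = 0.3,
                   ssb = 1), lambda = 1)
  ref <- study_reference()
  tab <- enumerate_options(m, ref, radius = 0, targets = c(3.45),
                           tolerance = 0.1)
  expect_equal(tab$n_total, 1 * nrow(tab$diet_grid))
  hit <- tab$options[tab$options$band == 3.45, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$fruit_veg, 1.5)
  expect_equal(hit$discretionary, 1.5)
  expect_equal(hit$ssb, 1.5)
  expect_equal(hit$diff, 3.45, tolerance = 1e-12)
  # overlapping bands are rejected
  expect_error(enumerate_options(m, ref, radius = 0, targets = c(1, 1.5),
                                 tolerance = 0.3), "overlap")
})

test_that("band counts shrink as the target grows for a monotone model", {
  m <- toy_model(c("(Intercept)" = 60, z1 = 1.2, z5 = 2, fruit_veg = 0.4,
                   discretionary = -0.4, ssb = -0.6), lambda = 1)
  ref <- study_reference()
  tab <- enumerate_options(m, ref, radius = 10,
                           targets = seq(0.5, 2.5, 0.5), tolerance = 0.25,
                           keep_bands = numeric(0))
  cts <- tab$counts[as.character(seq(0.5, 2.5, 0.5))]
  expect_true(all(diff(cts) <= 0))
  expect_equal(sum(tab$counts), tab$n_total)
})

test_that("the extreme positive band sits at the favourable grid corners", {
  m <- toy_model(c("(Intercept)" = 60, fruit_veg = 1, discretionary = -1,
                   ssb = -1), lambda = 1)
  ref <- study_reference()
  # max diff = 1.5 + 1.5 + 1 = 4 at the unique favourable corner
  tab <- enumerate_options(m, ref, radius = 0, targets = c(4),
                           tolerance = 0.25)
  top <- tab$options[tab$options$band == 4, ]
  expect_gte(nrow(top), 1)
  expect_true(all(top$fruit_veg == 1.5))
  expect_true(all(top$discretionary == -1.5))
  expect_true(all(top$ssb == -1))
})

test_that("per-behaviour summaries are complete percentage distributions", {
  m <- toy_model(c("(Intercept)" = 60, z5 = 2, fruit_veg = 0.5, ssb = -0.5),
                 lambda = 1)
  ref <- study_reference()
  tab <- enumerate_options(m, ref, radius = 10,
                           targets = c(0.5, 1, 1.5), tolerance = 0.25)
  s <- summarize_options(tab, 1)
  expect_gt(attr(s, "n_options"), 0)
  for (bh in unique(s$behaviour)) {
    expect_equal(sum(s$pct[s$behaviour == bh]), 100, tolerance = 1e-9)
    expect_equal(sum(s$n[s$behaviour == bh]), attr(s, "n_options"))
  }
  expect_setequal(unique(s$behaviour), c(time_parts(), diet_scores()))
  # empty band: explicit empty summary, not an error
  tab2 <- enumerate_options(m, ref, radius = 0, targets = c(2.4, 4.9),
                            tolerance = 0.2)
  s2 <- summarize_options(tab2, 4.9)
  expect_equal(nrow(s2), 0)
  expect_equal(attr(s2, "n_options"), 0)
})

test_that("closure is preserved: every reallocation keeps the day at 1440 minutes", {
  ref <- study_reference()
  g <- make_time_grid(ref, step = 10, radius = 20)
  pert <- sweep(g, 2, ref$time, "+")
  expect_true(all(rowSums(pert) == 1440))
  expect_true(all(pert > 0))
})

test_that("interactive filtering has exact subset semantics and order invariance", {
  m <- toy_model(c("(Intercept)" = 60, z1 = 1, z5 = 1.5, fruit_veg = 0.3,
                   ssb = -0.4), lambda = 1)
  ref <- study_reference()
  tab <- enumerate_options(m, ref, radius = 10,
                           targets = c(0.5, 1), tolerance = 0.25)
  st <- selection_state(tab, 0.5)
  full <- st$remaining
  # build a ~100-row state by pre-filtering on one behaviour if needed
  expect_gt(nrow(full), 10)

  # choosing a value present in every remaining row changes nothing
  av <- available_options(st)
  bh_all <- names(which(vapply(av, length, 1L) == 1L))
  if (length(bh_all)) {
    st1 <- select_option(st, bh_all[1], av[[bh_all[1]]])
    expect_equal(nrow(st1$remaining), nrow(full))
  }

  # exhaustive order-invariance over permutations of three selections
  set.seed(22)
  sel <- list()
  st_tmp <- st
  for (bh in c("physical_activity", "ssb", "sleep")) {
    a <- available_options(st_tmp)[[bh]]
    sel[[bh]] <- a[length(a)]
    st_tmp <- select_option(st_tmp, bh, sel[[bh]])
  }
  final_rows <- lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                            c(3, 1, 2), c(3, 2, 1)), function(perm) {
    s <- st
    for (k in perm) s <- select_option(s, names(sel)[k], sel[[k]])
    s$remaining
  })
  for (k in 2:6) expect_equal(final_rows[[k]], final_rows[[1]])
  expect_gt(nrow(final_rows[[1]]), 0)

  # selecting every behaviour pins down a consistent non-empty subset
  st_all <- st
  for (bh in st$behaviours) {
    a <- available_options(st_all)[[bh]]
    st_all <- select_option(st_all, bh, a[1])
  }
  expect_gt(nrow(st_all$remaining), 0)
  for (bh in st_all$behaviours) {
    expect_equal(unique(st_all$remaining[[bh]]),
                 st_all$choices[[bh]])
  }

  # unavailable choices error and list what is available
  expect_error(select_option(st, "ssb", 99), "available")
  expect_error(select_option(st, "not_a_behaviour", 0), "unknown")
})
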