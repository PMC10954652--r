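test_that("identity transition probabilities reproduce the start grid", {
  sch <- toy_scheme(3)
  spec <- landscape_spec(sch, 15, 15, start_props = c(0.5, 0.3, 0.2),
                         transition_probs = diag(3), cell_area = 1)
  lp <- gen_landscape_pair(spec, seed = 2)
  expect_identical(lp$grid_t0$values, lp$grid_t1$values)
  expect_true(all(lp$true_transitions$area[upper.tri(diag(3))] == 0))
})

test_that("tabulated transitions equal the generator's ground truth exactly", {
  sch <- toy_scheme(4)
  P <- matrix(c(0.7, 0.1, 0.1, 0.1,
                0.05, 0.8, 0.1, 0.05,
                0.1, 0.1, 0.7, 0.1,
                0.25, 0.05, 0.1, 0.6), 4, 4, byrow = TRUE)
  spec <- landscape_spec(sch, 200, 200, start_props = c(0.3, 0.3, 0.2, 0.2),
                         transition_probs = P, cell_area = 0.0009)
  lp <- gen_landscape_pair(spec, seed = 17)
  tm <- compute_transition_matrix(lp$grid_t0, lp$grid_t1)
  expect_equal(tm$area, lp$true_transitions$area)
})

test_that("realized transition frequencies match the prescribed P within 4 sigma", {
  sch <- toy_scheme(3)
  P <- matrix(c(0.8, 0.15, 0.05,
                0.1, 0.8, 0.1,
                0.05, 0.25, 0.7), 3, 3, byrow = TRUE)
  spec <- landscape_spec(sch, 120, 120, start_props = c(1, 1, 1) / 3,
                         transition_probs = P, cell_area = 1)
  lp <- gen_landscape_pair(spec, seed = 23)
  a <- lp$true_transitions$area
  for (i in 1:3) {
    n_i <- sum(a[i, ])
    for (j in 1:3) {
      phat <- a[i, j] / n_i
      tol <- 4 * sqrt(P[i, j] * (1 - P[i, j]) / n_i)
      expect_lt(abs(phat - P[i, j]), tol + 1e-9)
    }
  }
})

test_that("landscape generation is seed-deterministic and validates P", {
  sch <- toy_scheme(2)
  spec <- landscape_spec(sch, 10, 10, start_props = c(0.6, 0.4),
                         transition_probs = matrix(c(0.9, 0.1, 0.2, 0.8),
                                                   2, 2, byrow = TRUE))
  a <- gen_landscape_pair(spec, seed = 5)
  b <- gen_landscape_pair(spec, seed = 5)
  expect_identical(a$grid_t0$values, b$grid_t0$values)
  expect_identical(a$grid_t1$values, b$grid_t1$values)
  expect_error(landscape_spec(sch, 10, 10, start_props = c(0.6, 0.4),
                              transition_probs = matrix(0.4, 2, 2)),
               "row-stochastic")
  expect_error(landscape_spec(sch, 10, 10, start_props = c(0.6, 0.6),
                              transition_probs = diag(2)), "sum to 1")
})

test_that("zone lattice splits the landscape into contiguous column blocks", {
  sch <- toy_scheme(2)
  spec <- landscape_spec(sch, 6, 9, start_props = c(0.5, 0.5),
                         transition_probs = diag(2), n_zones = 3)
  lp <- gen_landscape_pair(spec, seed = 1)
  z <- lp$grid_t0$zones
  expect_setequal(unique(as.vector(z)), 1:3)
  # each column belongs to exactly one zone and zones are contiguous
  col_zone <- apply(z, 2, function(col) unique(col))
  expect_true(all(lengths(col_zone) == 1))
  expect_true(all(diff(unlist(col_zone)) >= 0))
})

test_that("survey generation snaps to the 5 admissible levels and recovers truth", {
  truth <- c(shrub = 0.45, crop = 0.40, water = 0.05)
  # zero dispersion: every response is the admissible level nearest truth
  s0 <- gen_survey(truth, n_respondents = 8, dispersion = 0, seed = 3)
  expect_setequal(unique(s0$score[s0$class_id == "shrub"]), 0.50)
  expect_setequal(unique(s0$score[s0$class_id == "water"]), 0.10)
  levels_ok <- s0$score %in% c(0.10, 0.25, 0.50, 0.75, 0.95)
  expect_true(all(levels_ok))

  # large panel with noise: aggregated mean within 2 SE of the truth
  s <- gen_survey(truth, n_respondents = 1000, dispersion = 0.15, seed = 9)
  expect_true(all(s$score %in% c(0.10, 0.25, 0.50, 0.75, 0.95)))
  agg <- aggregate_survey(s)
  for (cl in c("shrub", "crop")) {
    row <- agg[agg$class_id == cl, ]
    se <- row$sd / sqrt(row$n_respondents)
    expect_lt(abs(row$mean - truth[cl]), 2 * se + 0.02)
  }
})

test_that("plot-sample generation honours the zero-inflation rates", {
  all_zero <- gen_plot_samples(list(w = list(pi_zero = 1, lambda = 5)),
                               n_per_class = 60, seed = 4)
  expect_true(all(all_zero$density == 0))

  samp <- gen_plot_samples(list(g = list(pi_zero = 0.75, lambda = 9)),
                           n_per_class = 1000, seed = 4)
  x <- samp$density[samp$class_id == "g"]
  expect_true(all(x >= 0))
  zp <- mean(x == 0)
  tol <- 4 * sqrt(0.75 * 0.25 / 1000)
  expect_lt(abs(zp - 0.75), tol + 0.01)
})

test_that("seasonal stack recovers an exact line at zero noise and counts obs", {
  gs <- gen_seasonal_stack(n_years = 10, start_year = 2005, slope = 0.01,
                           intercept = -19.7, noise_sd = 0, n_obs = 6,
                           season = "spring", seed = 11)
  expect_equal(nrow(gs$stack), 10 * 6)
  expect_equal(as.integer(table(gs$stack$year)), rep(6L, 10))
  ser <- seasonal_series(gs$stack, "spring")
  ft <- fit_trend(ser$year, ser$value)
  expect_equal(ft$slope, 0.01, tolerance = 1e-12)
  expect_true(ft$degenerate)
})

test_that("null seasonal series reject near the nominal rate over seeds", {
  # strided seeds decorrelate the consecutive generator streams
  pvals <- vapply(1:500, function(k) {
    gs <- gen_seasonal_stack(n_years = 15, slope = 0, intercept = 0.4,
                             noise_sd = 0.02, n_obs = 5, seed = k * 977)
    ser <- seasonal_series(gs$stack, "spring")
    fit_trend(ser$year, ser$value)$p_value
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.025)
})

test_that("agreement-matrix rows live on the simplex at any concentration", {
  for (conc in c(0.5, 1, 20)) {
    am <- gen_agreement_matrix(5, 7, concentration = conc, seed = 13)
    expect_equal(rowSums(am), setNames(rep(1, 5), rownames(am)))
    expect_true(all(am >= 0 & am <= 1))
  }
  # infinite concentration gives exact one-hot rows recovering the identity
  am_inf <- gen_agreement_matrix(4, 4, concentration = Inf, seed = 1)
  expect_equal(unclass(am_inf), diag(4),
               ignore_attr = TRUE)
  # very high concentration concentrates mass on the own class
  am_hi <- gen_agreement_matrix(4, 4, concentration = 5000, seed = 2)
  expect_true(all(diag(unclass(am_hi)) > 0.9))
})

test_that("a full synthetic run reproduces the analytic expectation within 4 SE", {
  # landscape -> transition accounting -> per-class areas -> MC change
  sch <- toy_scheme(3)
  P <- matrix(c(0.85, 0.1, 0.05,
                0.05, 0.9, 0.05,
                0.1, 0.1, 0.8), 3, 3, byrow = TRUE)
  spec <- landscape_spec(sch, 80, 80, start_props = c(0.5, 0.3, 0.2),
                         transition_probs = P, cell_area = 0.5)
  lp <- gen_landscape_pair(spec, seed = 29)
  tm <- compute_transition_matrix(lp$grid_t0, lp$grid_t1)
  a0 <- rowSums(tm$area)
  a1 <- colSums(tm$area)
  dists <- toy_dists()
  ex <- expected_change(a0, a1, dists)
  mc <- mc_change(a0, a1, dists, mc_config(n_reps = 3000, seed = 31,
                                           truncation = "none"))
  s <- mc$summary[mc$summary$statistic == "change", ]
  expect_lt(abs(s$mean - ex$change), 4 * s$se)
})
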