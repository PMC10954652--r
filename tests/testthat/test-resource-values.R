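test_that("survey aggregation matches direct mean/SD formulas", {
  resp <- tibble::tibble(
    respondent_id = c("a", "b", "c"),
    class_id = "shrub", season = "spring", resource = "nectar",
    score = c(0.10, 0.50, 0.95)
  )
  agg <- aggregate_survey(resp)
  expect_equal(agg$mean, mean(c(0.10, 0.50, 0.95)))
  expect_equal(agg$sd, sd(c(0.10, 0.50, 0.95)))
  # frozen hand computation: mean 0.516667, sd 0.425245
  expect_equal(agg$mean, 0.5166667, tolerance = 1e-6)
  expect_equal(agg$sd, 0.4252450, tolerance = 1e-6)
  expect_equal(agg$n_respondents, 3L)
})

test_that("unanimous scores give zero SD and aggregation is exact on random sets", {
  resp <- tibble::tibble(respondent_id = letters[1:5], class_id = "x",
                         season = "fall", resource = "milkweed", score = 0.5)
  agg <- aggregate_survey(resp)
  expect_equal(agg$mean, 0.5)
  expect_equal(agg$sd, 0)

  set.seed(42)
  for (i in 1:5) {
    scores <- sample(c(0.10, 0.25, 0.50, 0.75, 0.95), 12, TRUE)
    r <- tibble::tibble(respondent_id = sprintf("r%02d", 1:12),
                        class_id = "x", season = "fall",
                        resource = "nectar", score = scores)
    a <- aggregate_survey(r)
    expect_equal(a$mean, mean(scores))
    expect_equal(a$sd, sd(scores))
  }
})

test_that("survey aggregation refuses undefined cells and invalid scores", {
  one <- tibble::tibble(respondent_id = "a", class_id = "x",
                        season = "fall", resource = "nectar", score = 0.5)
  expect_error(aggregate_survey(one), "fewer than 2")
  bad <- tibble::tibble(respondent_id = c("a", "b"), class_id = "x",
                        season = "fall", resource = "nectar",
                        score = c(0.5, 0.6))
  expect_error(aggregate_survey(bad), "admissible|must be one of")
})

test_that("crosswalk with the identity matrix is the identity map", {
  src <- tibble::tibble(class_id = c("s1", "s2", "s3"),
                        mean = c(0.2, 0.5, 0.8), sd = c(0.1, 0.2, 0.3))
  am <- diag(3)
  dimnames(am) <- list(c("s1", "s2", "s3"), c("s1", "s2", "s3"))
  out <- crosswalk_distributions(src, am)
  expect_equal(out$mean, src$mean)
  expect_equal(out$sd, src$sd)
})

test_that("crosswalk weighted averaging matches hand arithmetic", {
  src <- tibble::tibble(class_id = c("a", "b"), mean = c(0.2, 0.6),
                        sd = c(0.1, 0.3))
  am <- matrix(c(0.25, 0.75), 1, 2, dimnames = list("t", c("a", "b")))
  out <- crosswalk_distributions(src, am)
  expect_equal(out$mean, 0.25 * 0.2 + 0.75 * 0.6)  # 0.5
  expect_equal(out$sd, 0.25 * 0.1 + 0.75 * 0.3)    # 0.25
  # variance pooling differs and is never smaller than weighted-SD on
  # mixtures with separated means
  out_v <- crosswalk_distributions(src, am, pooling = "variance")
  expect_gt(out_v$sd, out$sd)
  expect_equal(out_v$mean, out$mean)
})

test_that("crosswalk means are convex combinations of source means", {
  set.seed(7)
  for (i in 1:10) {
    am <- gen_agreement_matrix(4, 6, concentration = 2, seed = i)
    src <- tibble::tibble(class_id = colnames(am),
                          mean = runif(6), sd = runif(6, 0, 0.3))
    out <- crosswalk_distributions(src, am)
    expect_true(all(out$mean >= min(src$mean) - 1e-12))
    expect_true(all(out$mean <= max(src$mean) + 1e-12))
  }
})

test_that("crosswalk rejects bad simplex rows and missing sources", {
  src <- tibble::tibble(class_id = "a", mean = 0.5, sd = 0.1)
  bad <- matrix(c(0.5, 0.4), 1, 2, dimnames = list("t", c("a", "b")))
  expect_error(crosswalk_distributions(src, bad), "sum to 1")
  ok <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("t", c("a", "b")))
  expect_error(crosswalk_distributions(src, ok), "no source distribution")
})

test_that("crop weighting collapses per-crop values with renormalized shares", {
  cv <- tibble::tibble(crop = c("corn", "cotton"), mean = c(0.2, 0.4),
                       sd = c(0.05, 0.15))
  out <- crop_weighted_value(cv, shares = c(corn = 0.5, cotton = 0.5))
  expect_equal(out$mean, 0.3)
  expect_equal(out$sd, 0.1)

  # single crop passes through unchanged
  single <- crop_weighted_value(cv[1, ], shares = c(corn = 0.37))
  expect_equal(single$mean, 0.2)

  # excluding a category renormalizes the remaining shares to 1
  cv3 <- tibble::tibble(crop = c("corn", "cotton", "sod"),
                        mean = c(0.2, 0.4, 0.9))
  out3 <- crop_weighted_value(cv3,
                              shares = c(corn = 0.3, cotton = 0.3, sod = 0.4),
                              exclude = "sod")
  expect_equal(sum(out3$shares), 1)
  expect_equal(out3$mean, 0.3)
  expect_error(crop_weighted_value(cv3, shares = c(sod = 1),
                                   exclude = "sod"), "no crops")
})

test_that("distribution moments agree with closed forms across families", {
  cases <- list(
    list("normal", list(mean = 0.4, sd = 0.2), 0.4, 0.2),
    list("beta", list(shape1 = 2, shape2 = 3), 0.4, sqrt(6 / (25 * 6))),
    list("exponential", list(rate = 0.5), 2, 2),
    list("negative_binomial", list(mu = 10, size = 2), 10, sqrt(10 + 50)),
    list("zero_inflated_poisson", list(pi = 0.7, lambda = 8),
         0.3 * 8, sqrt(0.3 * 8 * (1 + 0.7 * 8))),
    list("point_mass", list(value = 0), 0, 0)
  )
  for (cs in cases) {
    d <- resource_distribution(cs[[1]], cs[[2]])
    expect_equal(d$mean, cs[[3]], tolerance = 1e-12)
    expect_equal(d$sd, cs[[4]], tolerance = 1e-12)
  }
  # empirical check of the ZINB moments against a large sample
  d <- resource_distribution("zero_inflated_negative_binomial",
                             list(pi = 0.5, mu = 6, size = 1.5))
  set.seed(99)
  x <- sample_value(d, 2e5, truncation = "none")
  expect_equal(mean(x), d$mean, tolerance = 0.02)
  expect_equal(sd(x), d$sd, tolerance = 0.02)
})

test_that("sampling respects point masses, degenerate normals and truncation", {
  expect_equal(sample_value(resource_distribution("point_mass",
                                                  list(value = 0)), 10),
               rep(0, 10))
  expect_equal(sample_value(resource_distribution("normal",
                                                  list(mean = 0.5, sd = 0)),
                            5), rep(0.5, 5))
  set.seed(1)
  d <- resource_distribution("normal", list(mean = 0.5, sd = 0.6))
  clip <- sample_value(d, 5000, truncation = "clip")
  expect_true(all(clip >= 0 & clip <= 1))
  set.seed(1)
  rej <- sample_value(d, 5000, truncation = "reject")
  expect_true(all(rej >= 0 & rej <= 1))
  # clipping censors at the bounds; rejection never produces atoms there
  expect_gt(mean(clip == 0), 0)
  expect_equal(mean(rej == 0), 0)
  # density draws are never negative under default policy
  dd <- resource_distribution("normal", list(mean = 5, sd = 10),
                              units = "plants_per_ha")
  x <- sample_value(dd, 2000)
  expect_true(all(x >= 0))
})

test_that("large normal samples recover the distribution mean", {
  d <- resource_distribution("normal", list(mean = 0.447, sd = 0.272))
  set.seed(123)
  x <- sample_value(d, 1e5, truncation = "none")
  se <- 0.272 / sqrt(1e5)
  expect_lt(abs(mean(x) - 0.447), 4 * se)
})
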