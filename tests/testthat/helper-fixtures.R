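# Small fixtures shared across test files; everything is built in code.

toy_scheme <- function(k = 3) {
  class_scheme("toy", seq_len(k), paste0("c", seq_len(k)), nodata_code = 0L)
}

# 2x2 hand case: t0 = [[1,1],[2,2]], t1 = [[1,2],[2,2]], cell_area = 1.
# Enumerating the four cells: (1,1), (1,2), (2,2), (2,2).
hand_pair <- function() {
  sch <- toy_scheme(2)
  list(
    t0 = landcover_grid(matrix(c(1, 2, 1, 2), 2, 2), 1, sch),
    t1 = landcover_grid(matrix(c(1, 2, 2, 2), 2, 2), 1, sch)
  )
}

# brute-force transition tabulation: loop over cells, count pairs
brute_transitions <- function(grid_t0, grid_t1) {
  ids <- grid_t0$scheme$class_ids
  nd <- grid_t0$scheme$nodata_code
  out <- matrix(0, length(ids), length(ids),
                dimnames = list(from = as.character(ids),
                                to = as.character(ids)))
  for (i in seq_len(nrow(grid_t0$values))) {
    for (j in seq_len(ncol(grid_t0$values))) {
      a <- grid_t0$values[i, j]
      b <- grid_t1$values[i, j]
      if (a != nd && b != nd) {
        out[as.character(a), as.character(b)] <-
          out[as.character(a), as.character(b)] + grid_t0$cell_area
      }
    }
  }
  out
}

# closed-form OLS of value on year via the textbook sums
brute_ols <- function(year, value) {
  n <- length(year)
  sxx <- sum((year - mean(year))^2)
  slope <- sum((year - mean(year)) * (value - mean(value))) / sxx
  intercept <- mean(value) - slope * mean(year)
  resid <- value - intercept - slope * year
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  t <- slope / se
  list(slope = slope, intercept = intercept, se = se, t = t,
       p = 2 * stats::pt(-abs(t), n - 2))
}

# distributions for a tiny 3-class landscape used in MC tests
toy_dists <- function() {
  list(
    "1" = resource_distribution("normal", list(mean = 0.4, sd = 0.1),
                                class_id = "1"),
    "2" = resource_distribution("normal", list(mean = 0.7, sd = 0.2),
                                class_id = "2"),
    "3" = resource_distribution("point_mass", list(value = 0),
                                class_id = "3")
  )
}
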