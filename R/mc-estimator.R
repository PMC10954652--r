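# Monte Carlo propagation of land-cover area change into resource change.
# Each replicate draws one resource value per land-cover class, multiplies
# it into the class areas at both dates, sums over classes to an extent-wide
# total per date, and differences the dates. The replicate spread captures
# the uncertainty in the per-class resource values.

KM2_TO_HA <- 100

#' Monte Carlo configuration
#'
#' @param n_reps Number of replicates (default 5,000).
#' @param seed Optional integer seed; fixed seed gives bit-identical
#'   results.
#' @param draw_policy `"shared_across_years"` (default): one draw per class
#'   per replicate applied to both dates, so the change variance reflects
#'   value uncertainty applied to the area deltas. `"independent_per_year"`
#'   draws separately for each date.
#' @param truncation Truncation policy passed to [sample_value()].
#' @param unit_factor Multiplier applied to area x value products; use
#'   `km2_to_ha()` (100) when values are densities in plants/ha and areas in
#'   km^2, and 1 for unitless scores.
#' @return List of settings, classed `mc_config`.
#' @export
mc_config <- function(n_reps = 5000, seed = NULL,
                      draw_policy = c("shared_across_years",
                                      "independent_per_year"),
                      truncation = c("clip", "reject", "none"),
                      unit_factor = 1) {
  stopifnot(n_reps >= 1, unit_factor > 0)
  structure(
    list(n_reps = as.integer(n_reps), seed = seed,
         draw_policy = match.arg(draw_policy),
         truncation = match.arg(truncation),
         unit_factor = unit_factor),
    class = "mc_config"
  )
}

#' km^2 to hectare conversion factor
#' @return 100.
#' @export
km2_to_ha <- function() KM2_TO_HA

check_mc_inputs <- function(areas_t0, areas_t1, dists) {
  stopifnot(is.numeric(areas_t0), is.numeric(areas_t1))
  if (is.null(names(areas_t0)) || is.null(names(areas_t1))) {
    stop("area vectors must be named by class_id", call. = FALSE)
  }
  if (!setequal(names(areas_t0), names(areas_t1))) {
    stop("area vectors cover different class sets", call. = FALSE)
  }
  miss <- setdiff(names(areas_t0), names(dists))
  if (length(miss)) {
    stop("no resource distribution for class(es): ",
         paste(miss, collapse = ", "),
         " (zero-value classes need an explicit point_mass)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Analytic expectation of resource totals and change
#'
#' Closed-form counterpart of [mc_change()]: with per-class area `a_c` and
#' distribution mean `m_c`, the expected total is `sum(a_c * m_c * unit)`.
#' Serves as the oracle the Monte Carlo estimate must agree with (within
#' Monte Carlo error) and as a fast path when only point estimates are
#' needed.
#'
#' @param areas_t0,areas_t1 Named numeric vectors of per-class areas (km^2),
#'   same class sets.
#' @param dists Named list of [resource_distribution()] objects covering
#'   every class (zero-value classes as `point_mass(0)`).
#' @param unit_factor See [mc_config()].
#' @return List with `total_t0`, `total_t1`, `change`, `percent_change`.
#' @export
expected_change <- function(areas_t0, areas_t1, dists, unit_factor = 1) {
  check_mc_inputs(areas_t0, areas_t1, dists)
  cls <- names(areas_t0)
  means <- vapply(dists[cls], function(d) d$mean, numeric(1))
  total_t0 <- sum(areas_t0[cls] * means) * unit_factor
  total_t1 <- sum(areas_t1[cls] * means) * unit_factor
  change <- total_t1 - total_t0
  list(total_t0 = total_t0, total_t1 = total_t1, change = change,
       percent_change = if (total_t0 != 0) 100 * change / total_t0
                        else NA_real_)
}

#' Monte Carlo estimate of resource change between two dates
#'
#' For each replicate, a value is drawn from every class's resource
#' distribution, multiplied into the class areas at the start and end dates,
#' and summed over classes; change is the end total minus the start total
#' and percent change is relative to the replicate's start total. Summary
#' statistics are the replicate mean, SD, and SE = SD / sqrt(n_reps).
#'
#' @inheritParams expected_change
#' @param cfg An [mc_config()].
#' @return An `mc_result`: list with `replicates` (tibble: `total_t0`,
#'   `total_t1`, `change`, `percent_change`) and `summary` (tibble: one row
#'   per `statistic` in change / percent_change with `mean`, `sd`, `se`),
#'   plus the config. With `n_reps = 1` the SD/SE are `NA` and flagged.
#' @export
mc_change <- function(areas_t0, areas_t1, dists, cfg = mc_config()) {
  check_mc_inputs(areas_t0, areas_t1, dists)
  stopifnot(inherits(cfg, "mc_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cls <- names(areas_t0)
  n <- cfg$n_reps
  draws0 <- matrix(0, n, length(cls), dimnames = list(NULL, cls))
  for (c_i in cls) {
    draws0[, c_i] <- sample_value(dists[[c_i]], n, cfg$truncation)
  }
  draws1 <- if (cfg$draw_policy == "shared_across_years") {
    draws0
  } else {
    d1 <- matrix(0, n, length(cls), dimnames = list(NULL, cls))
    for (c_i in cls) {
      d1[, c_i] <- sample_value(dists[[c_i]], n, cfg$truncation)
    }
    d1
  }
  total_t0 <- as.vector(draws0 %*% areas_t0[cls]) * cfg$unit_factor
  total_t1 <- as.vector(draws1 %*% areas_t1[cls]) * cfg$unit_factor
  change <- total_t1 - total_t0
  percent <- ifelse(total_t0 != 0, 100 * change / total_t0, NA_real_)
  reps <- tibble::tibble(total_t0 = total_t0, total_t1 = total_t1,
                         change = change, percent_change = percent)
  summ <- function(x) {
    # a replicate whose start total is zero has no defined percent change;
    # such replicates are dropped from the percent summary and counted
    x <- x[is.finite(x)]
    k <- length(x)
    if (k < 2) c(mean = mean(x), sd = NA_real_, se = NA_real_, n_used = k)
    else c(mean = mean(x), sd = sd(x), se = sd(x) / sqrt(k), n_used = k)
  }
  s <- rbind(change = summ(change), percent_change = summ(percent))
  summary <- tibble::tibble(statistic = rownames(s),
                            mean = unname(s[, "mean"]),
                            sd = unname(s[, "sd"]),
                            se = unname(s[, "se"]),
                            n_used = as.integer(unname(s[, "n_used"])))
  structure(list(replicates = reps, summary = summary, config = cfg,
                 degenerate_se = n < 2),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("<mc_result> ", x$config$n_reps, " replicates (",
      x$config$draw_policy, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Zone-level Monte Carlo resource change
#'
#' Runs the replicate scheme of [mc_change()] over a set of zones that
#' partition the study extent. Within a replicate, one value is drawn per
#' class and applied to *every* zone, so zonal changes sum exactly to the
#' extent-wide change for that replicate and the reported zonal means sum
#' exactly to the extent-wide mean change.
#'
#' @param zonal_t0,zonal_t1 Numeric matrices of per-zone per-class areas
#'   (km^2), rows named by zone id and columns by class id.
#' @param dists,cfg As in [mc_change()].
#' @return Tibble with one row per zone: `zone_id`, `mean_change`,
#'   `se_change`, `mean_percent_change`, `se_percent_change`. Zones whose
#'   start total is zero in any replicate get `NA` percent change.
#' @export
zonal_change_map <- function(zonal_t0, zonal_t1, dists, cfg = mc_config()) {
  stopifnot(is.matrix(zonal_t0), is.matrix(zonal_t1),
            identical(dimnames(zonal_t0), dimnames(zonal_t1)))
  cls <- colnames(zonal_t0)
  if (is.null(cls) || is.null(rownames(zonal_t0))) {
    stop("zonal area matrices need zone rownames and class colnames",
         call. = FALSE)
  }
  check_mc_inputs(setNames(zonal_t0[1, ], cls), setNames(zonal_t1[1, ], cls),
                  dists)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_reps
  draw_matrix <- function() {
    m <- matrix(0, n, length(cls), dimnames = list(NULL, cls))
    for (c_i in cls) m[, c_i] <- sample_value(dists[[c_i]], n, cfg$truncation)
    m
  }
  draws0 <- draw_matrix()
  draws1 <- if (cfg$draw_policy == "shared_across_years") draws0
            else draw_matrix()
  # replicate x zone total matrices
  tot0 <- draws0 %*% t(zonal_t0) * cfg$unit_factor
  tot1 <- draws1 %*% t(zonal_t1) * cfg$unit_factor
  chg <- tot1 - tot0
  pct <- ifelse(tot0 != 0, 100 * chg / tot0, NA_real_)
  pmean <- function(x) if (any(is.finite(x))) mean(x[is.finite(x)]) else NA_real_
  pse <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) >= 2) sd(x) / sqrt(length(x)) else NA_real_
  }
  tibble::tibble(
    zone_id = rownames(zonal_t0),
    mean_change = unname(colMeans(chg)),
    se_change = unname(apply(chg, 2, sd)) / sqrt(n),
    mean_percent_change = unname(apply(pct, 2, pmean)),
    se_percent_change = unname(apply(pct, 2, pse))
  )
}

#' Rescale one region's zone changes onto another region's scale
#'
#' When two regions measure the same resource on incommensurate scales
#' (e.g. a unitless expert index vs field-measured plants/ha), region A's
#' zone-level changes are z-scored against their own mean and SD and then
#' de-standardized with region B's mean and SD, placing both regions on a
#' common range for joint mapping.
#'
#' @param values_a Numeric vector of zone changes to rescale.
#' @param values_b Numeric vector of zone changes defining the target scale
#'   (>= 2 finite values).
#' @return Numeric vector: `mean(b) + sd(b) * (a - mean(a)) / sd(a)`.
#' @export
rescale_cross_region <- function(values_a, values_b) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(b) < 2) {
    stop("reference region needs >= 2 finite zone values", call. = FALSE)
  }
  sd_a <- sd(a)
  if (!is.finite(sd_a) || sd_a == 0) {
    stop("cannot standardize: zone changes have zero spread", call. = FALSE)
  }
  mean(b) + sd(b) * (values_a - mean(a)) / sd_a
}
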