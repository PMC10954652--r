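# Bundled reference tables for the two study regions: per-class land-cover
# areas at the interval bookends (Mexico 2000-2020 on 8 GLAD-derived
# classes; Texas 2001-2019 on the 15 NLCD classes present in the study
# extent) and per-class seasonal resource values (survey-based 0-1 nectar /
# milkweed scores for Mexico; published floral scores and field-fit
# milkweed densities in plants/ha for Texas).

ref_path <- function(file) {
  system.file("extdata", file, package = "habitatshift", mustWork = TRUE)
}

#' Bundled per-class land-cover change areas for a study region
#'
#' @param region `"mexico"` (2000-2020 interval) or `"texas"` (2001-2019).
#' @return Tibble with `class_id`, `label`, `start_area_km2`,
#'   `end_area_km2`, `loss_km2`, `gain_km2`; attributes `start_year`,
#'   `end_year`, `interval_years` (the annualization divisor the published
#'   change table is consistent with: 19 for Mexico, 18 for Texas).
#' @export
reference_area_changes <- function(region = c("mexico", "texas")) {
  region <- match.arg(region)
  df <- tibble::as_tibble(utils::read.csv(
    ref_path(paste0("landcover_change_", region, ".csv")),
    stringsAsFactors = FALSE))
  yrs <- if (region == "mexico") c(2000L, 2020L, 19L) else c(2001L, 2019L, 18L)
  attr(df, "start_year") <- yrs[1]
  attr(df, "end_year") <- yrs[2]
  attr(df, "interval_years") <- yrs[3]
  df
}

#' Bundled per-class resource values for a study region
#'
#' @param region `"mexico"` or `"texas"`.
#' @return Tidy tibble with `class_id`, `resource` (`"nectar"` /
#'   `"milkweed"`), `season`, `mean`, `sd`, `units` (`"score"` or
#'   `"plants_per_ha"`).
#' @export
reference_resource_values <- function(region = c("mexico", "texas")) {
  region <- match.arg(region)
  tibble::as_tibble(utils::read.csv(
    ref_path(paste0("resource_values_", region, ".csv")),
    stringsAsFactors = FALSE))
}

#' Build a distribution registry from a mean/SD resource table
#'
#' Converts the rows of a resource-value table for one resource x season
#' into sampling distributions keyed by class:
#' * `units == "score"` rows become normal distributions (survey scores are
#'   approximately normal across respondents); rows with mean and SD both 0
#'   become point masses.
#' * `units == "plants_per_ha"` rows become moment-matched negative
#'   binomials (mean `m`, variance `s^2`, i.e. `mu = m`,
#'   `size = m^2 / (s^2 - m)`): densities are non-negative and heavily
#'   right-skewed, so a count family that preserves both moments on the
#'   correct support is used rather than a truncated normal, whose
#'   censoring would inflate the mean. Underdispersed rows (`s^2 <= m`)
#'   fall back to a Poisson (`pi = 0` zero-inflated Poisson); zero-mean
#'   rows become point masses.
#'
#' @param values Tibble as from [reference_resource_values()].
#' @param resource,season Which rows to use.
#' @return Named list of [resource_distribution()]s keyed by `class_id`.
#' @export
dists_from_table <- function(values, resource, season) {
  rows <- values[values$resource == resource & values$season == season, ]
  if (!nrow(rows)) {
    stop("no rows for resource '", resource, "', season '", season, "'",
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    if (r$mean == 0 && r$sd == 0) {
      return(resource_distribution("point_mass", list(value = 0),
                                   class_id = r$class_id, season = season,
                                   resource = resource, units = r$units))
    }
    if (identical(r$units, "score")) {
      resource_distribution("normal", list(mean = r$mean, sd = r$sd),
                            class_id = r$class_id, season = season,
                            resource = resource, units = r$units)
    } else if (r$sd^2 > r$mean) {
      resource_distribution(
        "negative_binomial",
        list(mu = r$mean, size = r$mean^2 / (r$sd^2 - r$mean)),
        class_id = r$class_id, season = season, resource = resource,
        units = r$units)
    } else {
      resource_distribution(
        "zero_inflated_poisson", list(pi = 0, lambda = r$mean),
        class_id = r$class_id, season = season, resource = resource,
        units = r$units)
    }
  })
  names(out) <- rows$class_id
  out
}

#' Named start/end area vectors from an area-change table
#'
#' @param areas Tibble as from [reference_area_changes()] or
#'   [read_area_table()].
#' @return List with named numeric vectors `t0` and `t1` (km^2).
#' @export
area_vectors <- function(areas) {
  list(t0 = setNames(areas$start_area_km2, areas$class_id),
       t1 = setNames(areas$end_area_km2, areas$class_id))
}
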