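# Seasonal median compositing and OLS year-trend fitting for climate and
# NDVI series. Seasons follow the migratory windows: spring = March-May,
# fall = September-November.

SEASON_MONTHS <- list(spring = 3:5, fall = 9:11)

#' Months belonging to a season
#' @param season `"spring"` (Mar-May) or `"fall"` (Sep-Nov).
#' @return Integer months.
#' @export
season_months <- function(season = c("spring", "fall")) {
  SEASON_MONTHS[[match.arg(season)]]
}

#' Per-pixel median composite of within-season observation layers
#'
#' Satellite variables arrive as repeated snapshots within a season (e.g.
#' ~11 eight-day NDVI layers across a three-month window). The seasonal
#' composite is the per-pixel median over all layers, ignoring missing
#' pixels; a pixel missing in every layer stays `NA`.
#'
#' @param layers List of numeric matrices of identical dimensions (or a 3-D
#'   array with layers along the third margin).
#' @return Matrix of per-pixel medians.
#' @export
seasonal_median_composite <- function(layers) {
  if (is.array(layers) && length(dim(layers)) == 3) {
    layers <- lapply(seq_len(dim(layers)[3]), function(i) layers[, , i])
  }
  stopifnot(is.list(layers), length(layers) >= 1)
  d <- dim(layers[[1]])
  if (!all(vapply(layers, function(m) identical(dim(m), d), logical(1)))) {
    stop("composite layers differ in shape", call. = FALSE)
  }
  arr <- array(unlist(layers), dim = c(d, length(layers)))
  apply(arr, c(1, 2), median, na.rm = TRUE)
}

#' Spatial median of a composite over a study-extent mask
#'
#' @param composite Numeric matrix (e.g. from
#'   [seasonal_median_composite()]).
#' @param mask Optional logical matrix of the same shape; `TRUE` pixels are
#'   inside the extent. Default: all pixels.
#' @return Scalar median over valid in-mask pixels.
#' @export
extent_median <- function(composite, mask = NULL) {
  stopifnot(is.matrix(composite))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(composite), ncol(composite))
  stopifnot(identical(dim(mask), dim(composite)))
  vals <- composite[mask]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("no valid pixel inside the mask", call. = FALSE)
  median(vals)
}

#' Build a yearly seasonal series from a dated observation table
#'
#' Collapses raw dated observations to one value per year: observations are
#' restricted to the months of the requested season and reduced by the
#' median within each year. For gridded inputs compose per-pixel first with
#' [seasonal_median_composite()] and reduce with [extent_median()]; this
#' helper covers the already-spatially-reduced case.
#'
#' @param obs Data frame with columns `date` (Date or parseable) and
#'   `value`.
#' @param season `"spring"` or `"fall"`.
#' @return Tibble with `year`, `value` (one row per year, increasing).
#' @export
seasonal_series <- function(obs, season = c("spring", "fall")) {
  season <- match.arg(season)
  stopifnot(all(c("date", "value") %in% names(obs)))
  d <- as.Date(obs$date)
  m <- as.integer(format(d, "%m"))
  keep <- m %in% SEASON_MONTHS[[season]]
  if (!any(keep)) {
    stop("no observations fall in the ", season, " season", call. = FALSE)
  }
  yr <- as.integer(format(d, "%Y"))[keep]
  v <- obs$value[keep]
  agg <- aggregate(v, by = list(year = yr), FUN = median, na.rm = TRUE)
  tibble::tibble(year = agg$year, value = agg$x)
}

#' OLS linear trend of a yearly seasonal series
#'
#' Fits `value ~ year` by ordinary least squares and reports the year slope
#' with its standard error, t statistic and two-sided p-value on n - 2
#' degrees of freedom. Year is centered internally for numerical stability;
#' the slope is unchanged and the reported intercept is on the original
#' year scale.
#'
#' @param years Integer years (strictly increasing recommended; duplicates
#'   rejected) or a data frame with `year` and `value` columns.
#' @param values Numeric values, same length as `years` (ignored when a
#'   data frame is given).
#' @return One-row tibble: `slope`, `slope_se`, `intercept`, `t_stat`,
#'   `p_value`, `n_years`, `degenerate` (`TRUE` for an exact-fit series
#'   whose residual variance is zero, making t and p meaningless).
#' @examples
#' fit_trend(2000:2024, 0.3 + 0.0026 * (0:24) + rnorm(25, 0, 0.01))
#' @export
fit_trend <- function(years, values = NULL) {
  if (is.data.frame(years)) {
    values <- years$value
    years <- years$year
  }
  stopifnot(length(years) == length(values))
  ok <- is.finite(years) & is.finite(values)
  years <- years[ok]; values <- values[ok]
  n <- length(years)
  if (n < 3) stop("trend fit needs at least 3 years", call. = FALSE)
  if (anyDuplicated(years)) stop("duplicate years in series", call. = FALSE)
  if (length(unique(years)) < 2 || sd(years) == 0) {
    stop("year vector is constant", call. = FALSE)
  }
  yc <- years - mean(years)
  fit <- lm(values ~ yc)
  # summary.lm warns on exact fits; degeneracy is detected and flagged below
  sf <- suppressWarnings(summary(fit))
  cf <- sf$coefficients
  slope <- cf["yc", "Estimate"]
  se <- cf["yc", "Std. Error"]
  degenerate <- sf$sigma < 1e-12 * max(1, sd(values))
  tstat <- if (se > 0) slope / se else Inf * sign(slope)
  pval <- if (se > 0) 2 * pt(-abs(tstat), df = n - 2) else 0
  tibble::tibble(
    slope = slope,
    slope_se = se,
    intercept = unname(coef(fit)[1]) - slope * mean(years),
    t_stat = tstat,
    p_value = pval,
    n_years = n,
    degenerate = degenerate
  )
}
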