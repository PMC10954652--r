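#' Define a land-cover classification scheme
#'
#' A scheme is an ordered set of integer class codes with labels, plus a
#' nodata code. Examples in this domain are the 8-class GLAD strata used for
#' Mexico, the 13-class NLCD subset present in the Texas study extent, and
#' the 14-class INEGI generalization used for the Mexico expert survey.
#'
#' @param scheme_id Character scalar naming the scheme (e.g. `"glad8"`).
#' @param class_ids Integer vector of unique class codes.
#' @param labels Optional character labels, same length as `class_ids`;
#'   defaults to `as.character(class_ids)`.
#' @param nodata_code Integer code marking cells with no valid class; must
#'   not collide with `class_ids`.
#' @return An object of class `class_scheme`.
#' @examples
#' class_scheme("toy", 1:3, c("forest", "crop", "urban"))
#' @export
class_scheme <- function(scheme_id, class_ids, labels = NULL, nodata_code = 0L) {
  class_ids <- as.integer(class_ids)
  stopifnot(length(scheme_id) == 1L, length(class_ids) >= 1L)
  if (anyDuplicated(class_ids)) {
    stop("class_ids must be unique", call. = FALSE)
  }
  nodata_code <- as.integer(nodata_code)
  if (nodata_code %in% class_ids) {
    stop("nodata_code must not be one of the class_ids", call. = FALSE)
  }
  if (is.null(labels)) labels <- as.character(class_ids)
  stopifnot(length(labels) == length(class_ids))
  structure(
    list(scheme_id = scheme_id, class_ids = class_ids,
         labels = labels, nodata_code = nodata_code),
    class = "class_scheme"
  )
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("<class_scheme '", x$scheme_id, "'> ", length(x$class_ids),
      " classes, nodata = ", x$nodata_code, "\n", sep = "")
  invisible(x)
}

#' Wrap a categorical raster as a land-cover grid
#'
#' Grids are integer matrices of class codes on a regular lattice; cell
#' geometry enters only through `cell_area` (km^2 per cell, e.g. 0.0009 for
#' a 30-m raster). Grids must already be aligned: no reprojection or
#' resampling is performed.
#'
#' @param values Integer matrix of class codes.
#' @param cell_area Positive area of one cell in km^2.
#' @param scheme A [class_scheme()].
#' @param zones Optional integer matrix of zone ids (county / municipality),
#'   identical in shape to `values`.
#' @return An object of class `landcover_grid`.
#' @export
landcover_grid <- function(values, cell_area, scheme, zones = NULL) {
  stopifnot(is.matrix(values), inherits(scheme, "class_scheme"))
  if (!is.numeric(cell_area) || length(cell_area) != 1L || cell_area <= 0) {
    stop("cell_area must be a single positive number (km^2)", call. = FALSE)
  }
  values <- matrix(as.integer(values), nrow = nrow(values))
  ok <- values %in% c(scheme$class_ids, scheme$nodata_code)
  if (!all(ok)) {
    bad <- unique(values[!ok])
    stop("grid contains codes outside the scheme: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(zones)) {
    stopifnot(is.matrix(zones))
    if (!identical(dim(zones), dim(values))) {
      stop("zone lattice must have the same shape as the class lattice",
           call. = FALSE)
    }
    zones <- matrix(as.integer(zones), nrow = nrow(zones))
  }
  structure(
    list(values = values, cell_area = cell_area, scheme = scheme,
         zones = zones),
    class = "landcover_grid"
  )
}

#' @export
print.landcover_grid <- function(x, ...) {
  cat("<landcover_grid> ", nrow(x$values), "x", ncol(x$values),
      " cells of ", x$cell_area, " km^2, scheme '", x$scheme$scheme_id, "'",
      if (!is.null(x$zones)) paste0(", ", length(unique(as.vector(x$zones))),
                                    " zones"),
      "\n", sep = "")
  invisible(x)
}

check_grid_pair <- function(grid_t0, grid_t1) {
  stopifnot(inherits(grid_t0, "landcover_grid"),
            inherits(grid_t1, "landcover_grid"))
  if (!identical(dim(grid_t0$values), dim(grid_t1$values))) {
    stop("grids differ in shape: ", paste(dim(grid_t0$values), collapse = "x"),
         " vs ", paste(dim(grid_t1$values), collapse = "x"), call. = FALSE)
  }
  if (!identical(grid_t0$scheme$scheme_id, grid_t1$scheme$scheme_id) ||
      !identical(grid_t0$scheme$class_ids, grid_t1$scheme$class_ids)) {
    stop("grids use different classification schemes", call. = FALSE)
  }
  if (grid_t0$cell_area != grid_t1$cell_area) {
    stop("grids differ in cell_area", call. = FALSE)
  }
  invisible(TRUE)
}

new_transition_matrix <- function(area, start_year, end_year, labels = NULL) {
  structure(
    list(area = area, start_year = start_year, end_year = end_year,
         labels = labels),
    class = "transition_matrix"
  )
}

#' Tabulate class-to-class transitions between two dates
#'
#' Counts every cell's (class at t0, class at t1) pair — including no-change
#' cells on the diagonal — and converts counts to areas. A cell that is
#' nodata at either date is excluded entirely, so the matrix marginals stay
#' interpretable: row sums are start-date class areas and column sums are
#' end-date class areas over the jointly valid extent.
#'
#' @param grid_t0,grid_t1 [landcover_grid()]s of identical shape, scheme and
#'   cell area.
#' @param start_year,end_year Optional integer years stored with the result.
#' @return A `transition_matrix`: square area matrix (km^2) with one
#'   row/column per scheme class, rows = start class, columns = end class.
#' @export
compute_transition_matrix <- function(grid_t0, grid_t1,
                                      start_year = NA_integer_,
                                      end_year = NA_integer_) {
  check_grid_pair(grid_t0, grid_t1)
  sch <- grid_t0$scheme
  v0 <- as.vector(grid_t0$values)
  v1 <- as.vector(grid_t1$values)
  keep <- v0 != sch$nodata_code & v1 != sch$nodata_code
  if (!any(keep)) {
    stop("no cell is valid at both dates; transition matrix would be empty",
         call. = FALSE)
  }
  f0 <- factor(v0[keep], levels = sch$class_ids)
  f1 <- factor(v1[keep], levels = sch$class_ids)
  counts <- table(from = f0, to = f1)
  area <- unclass(counts) * grid_t0$cell_area
  dimnames(area) <- list(from = as.character(sch$class_ids),
                         to = as.character(sch$class_ids))
  new_transition_matrix(area, as.integer(start_year), as.integer(end_year),
                        labels = sch$labels)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> ", nrow(x$area), " classes, total area ",
      format(sum(x$area), big.mark = ","), " km^2",
      if (!is.na(x$start_year)) paste0(" (", x$start_year, " -> ",
                                       x$end_year, ")"),
      "\n", sep = "")
  print(round(x$area, 3))
  invisible(x)
}

#' Per-class change statistics from a transition matrix
#'
#' Derives the bookkeeping columns of a land-cover change table: for each
#' class, loss is the off-diagonal row sum (area leaving the class), gain the
#' off-diagonal column sum (area entering), net = gain - loss, gross =
#' gain + loss, and percent change is net relative to the start-date area on
#' the 0-100 scale. `annual` is net / `interval_years` — the divisor is an
#' explicit argument because annualization conventions differ (an interval
#' labelled 2000-2020 may be annualized over 19 or 20 years).
#'
#' @param tm A `transition_matrix` from [compute_transition_matrix()].
#' @param interval_years Positive number of years used to annualize.
#' @return A tibble with one row per class: `class_id`, `start_area`,
#'   `end_area`, `loss`, `gain`, `net`, `gross`, `annual`, `percent_annual`,
#'   `percent_total`. Areas in km^2; percents on the 0-100 scale. Classes
#'   with zero start area get `NA` percents (undefined, not 0).
#' @export
summarize_change <- function(tm, interval_years) {
  stopifnot(inherits(tm, "transition_matrix"))
  a <- tm$area
  change_summary(
    class_id = rownames(a),
    start_area = rowSums(a),
    end_area = colSums(a),
    loss = rowSums(a) - diag(a),
    gain = colSums(a) - diag(a),
    interval_years = interval_years
  )
}

#' Change statistics from start/end/loss/gain area columns
#'
#' The table-driven counterpart of [summarize_change()], for published or
#' pre-tabulated per-class areas where the full transition matrix is not
#' available. Net is defined as gain - loss; `end_area` defaults to
#' `start_area + net` and, when supplied, is retained as given (printed
#' tables are often independently rounded).
#'
#' @param class_id Class identifiers.
#' @param start_area,loss,gain Per-class areas, km^2.
#' @param end_area Optional end-date areas, km^2.
#' @param interval_years Positive annualization divisor.
#' @return Tibble as in [summarize_change()].
#' @export
change_summary <- function(class_id, start_area, loss, gain,
                           end_area = NULL, interval_years) {
  stopifnot(length(interval_years) == 1L, interval_years > 0)
  n <- length(class_id)
  stopifnot(length(start_area) == n, length(loss) == n, length(gain) == n)
  if (any(loss < 0) || any(gain < 0) || any(start_area < 0)) {
    stop("areas must be non-negative", call. = FALSE)
  }
  start_area <- unname(as.numeric(start_area))
  loss <- unname(as.numeric(loss))
  gain <- unname(as.numeric(gain))
  net <- gain - loss
  if (is.null(end_area)) end_area <- start_area + net
  end_area <- unname(as.numeric(end_area))
  percent_total <- ifelse(start_area > 0, 100 * net / start_area, NA_real_)
  tibble::tibble(
    class_id = as.character(class_id),
    start_area = as.numeric(start_area),
    end_area = as.numeric(end_area),
    loss = as.numeric(loss),
    gain = as.numeric(gain),
    net = net,
    gross = gain + loss,
    annual = net / interval_years,
    percent_annual = percent_total / interval_years,
    percent_total = percent_total
  )
}

#' Per-zone change summaries
#'
#' Splits the paired grids by the zone lattice (counties in Texas,
#' municipalities in Mexico) and tabulates a transition matrix and change
#' summary within each zone. Zonal transition matrices sum exactly to the
#' extent-wide matrix because every jointly valid cell belongs to exactly
#' one zone.
#'
#' @inheritParams compute_transition_matrix
#' @param interval_years Annualization divisor passed to
#'   [summarize_change()].
#' @return A list with `summary` — a tibble of per-zone per-class change
#'   rows plus `percent_gross` (100 * gross / start area) — and `matrices`,
#'   the named list of per-zone `transition_matrix` objects.
#' @export
zonal_change <- function(grid_t0, grid_t1, interval_years = 1) {
  check_grid_pair(grid_t0, grid_t1)
  if (is.null(grid_t0$zones)) {
    stop("zonal_change requires a zone lattice on grid_t0", call. = FALSE)
  }
  zones <- as.vector(grid_t0$zones)
  zone_ids <- sort(unique(zones))
  mats <- lapply(zone_ids, function(z) {
    idx <- matrix(zones == z, nrow = nrow(grid_t0$values))
    sub0 <- grid_t0$values
    sub1 <- grid_t1$values
    # mask out-of-zone cells as nodata so the shared tabulator applies
    sub0[!idx] <- grid_t0$scheme$nodata_code
    sub1[!idx] <- grid_t1$scheme$nodata_code
    g0 <- landcover_grid(sub0, grid_t0$cell_area, grid_t0$scheme)
    g1 <- landcover_grid(sub1, grid_t1$cell_area, grid_t1$scheme)
    compute_transition_matrix(g0, g1)
  })
  names(mats) <- as.character(zone_ids)
  summ <- dplyr::bind_rows(lapply(zone_ids, function(z) {
    s <- summarize_change(mats[[as.character(z)]], interval_years)
    s$zone_id <- z
    s$percent_gross <- ifelse(s$start_area > 0,
                              100 * s$gross / s$start_area, NA_real_)
    dplyr::relocate(s, "zone_id")
  }))
  list(summary = summ, matrices = mats)
}

#' Tidy long-format export of a transition matrix
#'
#' One row per observed (from, to) flow with positive area; the diagonal
#' (no-change) flows are included. This is the tabular form behind
#' chord-diagram figures of land-cover transitions.
#'
#' @param tm A `transition_matrix`.
#' @return Tibble with columns `from_class`, `to_class`, `area`.
#' @export
transitions_long <- function(tm) {
  stopifnot(inherits(tm, "transition_matrix"))
  df <- tibble::as_tibble(as.data.frame.table(tm$area,
                                              responseName = "area",
                                              stringsAsFactors = FALSE))
  names(df) <- c("from_class", "to_class", "area")
  df[df$area > 0, ]
}

#' Rebuild a transition matrix from its tidy long form
#'
#' Inverse of [transitions_long()]: flows absent from the table are zero.
#'
#' @param df Tibble with `from_class`, `to_class`, `area`.
#' @param class_ids Ordered class codes defining the matrix dimensions;
#'   defaults to the sorted union of classes present.
#' @param start_year,end_year Optional years stored with the result.
#' @return A `transition_matrix`.
#' @export
transitions_from_long <- function(df, class_ids = NULL,
                                  start_year = NA_integer_,
                                  end_year = NA_integer_) {
  stopifnot(all(c("from_class", "to_class", "area") %in% names(df)))
  if (is.null(class_ids)) {
    class_ids <- sort(unique(c(df$from_class, df$to_class)))
  }
  k <- length(class_ids)
  area <- matrix(0, k, k, dimnames = list(from = as.character(class_ids),
                                          to = as.character(class_ids)))
  area[cbind(as.character(df$from_class), as.character(df$to_class))] <-
    df$area
  new_transition_matrix(area, as.integer(start_year), as.integer(end_year))
}

#' Read a per-class area table from CSV
#'
#' Expected columns: `class_id`, `start_area_km2`, `end_area_km2` and
#' optionally `loss_km2`, `gain_km2`, `label`. This is the entry point for
#' table-driven runs where only published class areas, not rasters, are
#' available.
#'
#' @param path CSV file path.
#' @return Tibble with the columns found.
#' @export
read_area_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("class_id", "start_area_km2", "end_area_km2")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("area table ", path, " lacks columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}
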