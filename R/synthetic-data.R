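# Synthetic-data generators. Every generator is seed-deterministic and
# returns its ground truth alongside the data, so each pipeline stage can be
# tested against known answers without any external download. Cells are
# spatially independent (no autocorrelation): the downstream pipeline is
# area-based, so patchiness does not affect any tested statistic.

#' Specification for a paired synthetic landscape
#'
#' @param scheme A [class_scheme()].
#' @param nrow,ncol Grid dimensions.
#' @param start_props Named (by class id) mixing proportions for the start
#'   date; must sum to 1.
#' @param transition_probs Row-stochastic matrix `P[i, j]` giving the
#'   probability that a cell of class i at the start date is class j at the
#'   end date; dimnames = class ids.
#' @param cell_area Cell area in km^2 (default 0.0009, a 30-m cell).
#' @param n_zones Number of contiguous column-block zones (mimicking
#'   counties).
#' @return List of settings, classed `landscape_spec`.
#' @export
landscape_spec <- function(scheme, nrow = 100, ncol = 100,
                           start_props, transition_probs,
                           cell_area = 0.0009, n_zones = 1) {
  stopifnot(inherits(scheme, "class_scheme"), nrow >= 1, ncol >= 1,
            n_zones >= 1, cell_area > 0)
  k <- length(scheme$class_ids)
  ids <- as.character(scheme$class_ids)
  stopifnot(length(start_props) == k, is.matrix(transition_probs),
            all(dim(transition_probs) == k))
  if (is.null(names(start_props))) names(start_props) <- ids
  if (is.null(rownames(transition_probs))) {
    dimnames(transition_probs) <- list(ids, ids)
  }
  if (abs(sum(start_props) - 1) > 1e-9) {
    stop("start_props must sum to 1", call. = FALSE)
  }
  if (any(transition_probs < 0) ||
      any(abs(rowSums(transition_probs) - 1) > 1e-9)) {
    stop("transition_probs must be row-stochastic", call. = FALSE)
  }
  structure(list(scheme = scheme, nrow = nrow, ncol = ncol,
                 start_props = start_props[ids],
                 transition_probs = transition_probs[ids, ids],
                 cell_area = cell_area, n_zones = n_zones),
            class = "landscape_spec")
}

#' Generate a paired two-date landscape with known transitions
#'
#' Start-date cells are drawn independently from the mixing proportions;
#' each end-date cell is drawn from the transition-probability row of its
#' start class. The realized (not expected) transition areas are returned
#' as ground truth, so [compute_transition_matrix()] on the pair must
#' reproduce them exactly.
#'
#' @param spec A [landscape_spec()].
#' @param seed Integer seed.
#' @return List with `grid_t0`, `grid_t1` ([landcover_grid()]s sharing a
#'   zone lattice of contiguous column blocks) and `true_transitions`
#'   (a `transition_matrix` of realized areas).
#' @export
gen_landscape_pair <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(seed)
  ids <- spec$scheme$class_ids
  n <- spec$nrow * spec$ncol
  v0 <- sample(ids, n, replace = TRUE, prob = spec$start_props)
  P <- spec$transition_probs
  v1 <- integer(n)
  for (i in seq_along(ids)) {
    idx <- which(v0 == ids[i])
    if (length(idx)) {
      v1[idx] <- sample(ids, length(idx), replace = TRUE, prob = P[i, ])
    }
  }
  m0 <- matrix(v0, spec$nrow, spec$ncol)
  m1 <- matrix(v1, spec$nrow, spec$ncol)
  zone_of_col <- rep(seq_len(spec$n_zones),
                     each = ceiling(spec$ncol / spec$n_zones),
                     length.out = spec$ncol)
  zones <- matrix(rep(zone_of_col, each = spec$nrow), spec$nrow, spec$ncol)
  counts <- table(from = factor(v0, levels = ids),
                  to = factor(v1, levels = ids))
  area <- unclass(counts) * spec$cell_area
  dimnames(area) <- list(from = as.character(ids), to = as.character(ids))
  list(
    grid_t0 = landcover_grid(m0, spec$cell_area, spec$scheme, zones),
    grid_t1 = landcover_grid(m1, spec$cell_area, spec$scheme, zones),
    true_transitions = new_transition_matrix(area, NA_integer_, NA_integer_)
  )
}

#' Generate synthetic expert-survey responses
#'
#' Each respondent's score for a class is the admissible 5-level score
#' nearest to the class's true mean plus Gaussian respondent noise, so at
#' zero dispersion every response is the level nearest the truth and
#' [aggregate_survey()] recovers the (level-rounded) truth exactly.
#'
#' @param true_means Named numeric vector in [0, 1] of per-class true
#'   values.
#' @param n_respondents Number of respondents (the study this emulates used
#'   30).
#' @param dispersion SD of the respondent noise on the score scale.
#' @param season,resource Labels attached to the responses.
#' @param seed Integer seed.
#' @return Tibble in the [aggregate_survey()] input layout; scores only
#'   ever take the 5 admissible levels.
#' @export
gen_survey <- function(true_means, n_respondents = 30, dispersion = 0.15,
                       season = "spring", resource = "nectar", seed = 1L) {
  stopifnot(all(true_means >= 0 & true_means <= 1), n_respondents >= 1,
            dispersion >= 0)
  if (is.null(names(true_means))) {
    names(true_means) <- paste0("class_", seq_along(true_means))
  }
  set.seed(seed)
  grid <- expand.grid(respondent_id = sprintf("r%03d",
                                              seq_len(n_respondents)),
                      class_id = names(true_means),
                      stringsAsFactors = FALSE)
  latent <- true_means[grid$class_id] +
    rnorm(nrow(grid), 0, dispersion)
  snap <- vapply(latent, function(x) {
    SCORE_LEVELS[which.min(abs(SCORE_LEVELS - x))]
  }, numeric(1))
  tibble::tibble(
    respondent_id = grid$respondent_id,
    class_id = grid$class_id,
    season = season,
    resource = resource,
    score = snap
  )
}

#' Generate zero-inflated milkweed plot samples
#'
#' Emulates field plot-density compilations dominated by zeros (60-91% per
#' class in the data this mirrors): with probability `pi_zero` a plot is an
#' exact zero, otherwise its density is drawn from the class's count
#' distribution.
#'
#' @param class_specs Named list (by class id); each element a list with
#'   `pi_zero` and either `lambda` (Poisson counts) or `mu` and `size`
#'   (negative binomial counts).
#' @param n_per_class Samples per class (recycled).
#' @param seed Integer seed.
#' @return Tibble with `sample_id`, `class_id`, `density` (plants/ha),
#'   `year`, `source`, `include`; attribute `truth` restates the specs.
#' @export
gen_plot_samples <- function(class_specs, n_per_class = 100, seed = 1L) {
  stopifnot(is.list(class_specs), length(class_specs) >= 1)
  n_per_class <- rep_len(n_per_class, length(class_specs))
  set.seed(seed)
  rows <- Map(function(cl, spec, n) {
    stopifnot(spec$pi_zero >= 0, spec$pi_zero <= 1)
    zero <- runif(n) < spec$pi_zero
    pos <- if (!is.null(spec$lambda)) rpois(n, spec$lambda)
           else rnbinom(n, mu = spec$mu, size = spec$size)
    tibble::tibble(class_id = cl, density = ifelse(zero, 0, pos))
  }, names(class_specs), class_specs, n_per_class)
  out <- dplyr::bind_rows(rows)
  out$sample_id <- sprintf("s%05d", seq_len(nrow(out)))
  out$year <- 2015L
  out$source <- "synthetic"
  out$include <- TRUE
  attr(out, "truth") <- class_specs
  out[, c("sample_id", "class_id", "density", "year", "source", "include")]
}

#' Generate a seasonal observation stack with a known linear trend
#'
#' Produces `n_obs` within-season observations per year scattered around a
#' yearly mean that follows `intercept + slope * year`, plus the true
#' noise-free series. Compositing the stack by year-median and fitting
#' [fit_trend()] recovers the slope within sampling error.
#'
#' @param n_years Number of consecutive years (>= 3).
#' @param start_year First calendar year.
#' @param slope,intercept Linear trend of the yearly mean (per year /
#'   at year 0).
#' @param noise_sd SD of observation noise (>= 0).
#' @param n_obs Observations per season-year (e.g. ~11 for 8-day
#'   composites).
#' @param season `"spring"` or `"fall"`.
#' @param seed Integer seed.
#' @return List with `stack` (tibble: `date`, `year`, `value`) and
#'   `true_series` (tibble: `year`, `value`).
#' @export
gen_seasonal_stack <- function(n_years = 25, start_year = 1997,
                               slope = 0.0026, intercept = 0.3,
                               noise_sd = 0.01, n_obs = 11,
                               season = c("spring", "fall"), seed = 1L) {
  season <- match.arg(season)
  stopifnot(n_years >= 3, noise_sd >= 0, n_obs >= 1)
  set.seed(seed)
  years <- start_year + seq_len(n_years) - 1L
  months <- SEASON_MONTHS[[season]]
  rows <- lapply(years, function(y) {
    mu <- intercept + slope * y
    mo <- sample(months, n_obs, replace = TRUE)
    dy <- sample(1:28, n_obs, replace = TRUE)
    tibble::tibble(
      date = as.Date(sprintf("%d-%02d-%02d", y, mo, dy)),
      year = y,
      value = mu + rnorm(n_obs, 0, noise_sd)
    )
  })
  list(
    stack = dplyr::bind_rows(rows),
    true_series = tibble::tibble(year = years,
                                 value = intercept + slope * years)
  )
}

#' Generate a random agreement matrix
#'
#' Rows are independent draws from a symmetric Dirichlet, optionally pulled
#' toward one-hot rows: at high concentration on a square matrix the result
#' approaches a permutation-free identity-like crosswalk (each target class
#' dominated by its same-index source class).
#'
#' @param n_target,n_source Numbers of target and source classes (>= 1).
#' @param concentration Dirichlet weight put on the "own" source class of
#'   each target row (diagonal index, recycled for rectangular matrices);
#'   the remaining classes share weight 1 each. `Inf` gives exact one-hot
#'   rows.
#' @param seed Integer seed.
#' @return An [agreement_matrix()] with rows `t1..`, columns `s1..`.
#' @export
gen_agreement_matrix <- function(n_target, n_source, concentration = 1,
                                 seed = 1L) {
  stopifnot(n_target >= 1, n_source >= 1, concentration > 0)
  set.seed(seed)
  m <- matrix(0, n_target, n_source,
              dimnames = list(paste0("t", seq_len(n_target)),
                              paste0("s", seq_len(n_source))))
  for (i in seq_len(n_target)) {
    own <- ((i - 1) %% n_source) + 1
    if (is.infinite(concentration)) {
      m[i, own] <- 1
    } else {
      alpha <- rep(1, n_source)
      alpha[own] <- concentration
      g <- rgamma(n_source, shape = alpha, rate = 1)
      m[i, ] <- g / sum(g)
    }
  }
  agreement_matrix(m)
}
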