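#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rbeta rexp rpois rnbinom rbinom runif dpois
#'   dnbinom dexp optim qnorm pt sd median quantile aggregate lm
#'   coef rgamma
#' @importFrom dplyr .data
#' @importFrom utils modifyList
NULL

#' @importFrom stats setNames
NULL

# Admissible expert-survey score levels (a 5-level rating scale whose labels
# double as 0-1 scores).
SCORE_LEVELS <- c(0.10, 0.25, 0.50, 0.75, 0.95)

dist_families <- c("normal", "beta", "exponential", "negative_binomial",
                   "zero_inflated_poisson", "zero_inflated_negative_binomial",
                   "zero_inflated_bernoulli", "point_mass")

#' Construct a per-class resource distribution
#'
#' A `resource_distribution` describes the value of one land-cover class for
#' one resource in one season: either a unitless 0-1 suitability score
#' (expert-derived nectar or milkweed indices) or a milkweed density in
#' plants/ha (field-count fits). The family and parameters determine the
#' closed-form mean and SD, which are stored alongside.
#'
#' Supported families and parameters:
#' * `normal`: `mean`, `sd`
#' * `beta`: `shape1`, `shape2`
#' * `exponential`: `rate`
#' * `negative_binomial`: `mu`, `size`
#' * `zero_inflated_poisson`: `pi` (extra-zero probability), `lambda`
#' * `zero_inflated_negative_binomial`: `pi`, `mu`, `size`
#' * `zero_inflated_bernoulli`: `pi`, `prob` (presence model)
#' * `point_mass`: `value`
#'
#' @param family One of the families above.
#' @param params Named list of family parameters.
#' @param class_id,season,resource Optional identifying metadata.
#' @param units `"score"` (0-1, unitless) or `"plants_per_ha"`.
#' @return An object of class `resource_distribution` with `mean` and `sd`.
#' @examples
#' resource_distribution("normal", list(mean = 0.447, sd = 0.272))
#' resource_distribution("zero_inflated_poisson", list(pi = 0.7, lambda = 8),
#'                       units = "plants_per_ha")
#' @export
resource_distribution <- function(family, params, class_id = NA_character_,
                                  season = NA_character_,
                                  resource = NA_character_,
                                  units = "score") {
  family <- match.arg(family, dist_families)
  mom <- dist_moments(family, params)
  structure(
    list(family = family, params = params, mean = mom$mean, sd = mom$sd,
         class_id = class_id, season = season, resource = resource,
         units = units),
    class = "resource_distribution"
  )
}

#' @export
print.resource_distribution <- function(x, ...) {
  cat("<resource_distribution> ", x$family, "(",
      paste(names(x$params), signif(unlist(x$params), 4), sep = "=",
            collapse = ", "),
      "): mean ", signif(x$mean, 4), ", sd ", signif(x$sd, 4),
      " [", x$units, "]\n", sep = "")
  invisible(x)
}

#' Closed-form moments for a distribution family
#'
#' @param family,params As in [resource_distribution()].
#' @return List with `mean` and `sd`.
#' @export
dist_moments <- function(family, params) {
  p <- params
  switch(family,
    normal = {
      stopifnot(p$sd >= 0)
      list(mean = p$mean, sd = p$sd)
    },
    beta = {
      stopifnot(p$shape1 > 0, p$shape2 > 0)
      m <- p$shape1 / (p$shape1 + p$shape2)
      v <- p$shape1 * p$shape2 /
        ((p$shape1 + p$shape2)^2 * (p$shape1 + p$shape2 + 1))
      list(mean = m, sd = sqrt(v))
    },
    exponential = {
      stopifnot(p$rate > 0)
      list(mean = 1 / p$rate, sd = 1 / p$rate)
    },
    negative_binomial = {
      stopifnot(p$mu >= 0, p$size > 0)
      list(mean = p$mu, sd = sqrt(p$mu + p$mu^2 / p$size))
    },
    zero_inflated_poisson = {
      stopifnot(p$pi >= 0, p$pi <= 1, p$lambda >= 0)
      m <- (1 - p$pi) * p$lambda
      v <- (1 - p$pi) * p$lambda * (1 + p$pi * p$lambda)
      list(mean = m, sd = sqrt(v))
    },
    zero_inflated_negative_binomial = {
      stopifnot(p$pi >= 0, p$pi <= 1, p$mu >= 0, p$size > 0)
      m <- (1 - p$pi) * p$mu
      v <- (1 - p$pi) * p$mu * (1 + p$mu / p$size + p$pi * p$mu)
      list(mean = m, sd = sqrt(v))
    },
    zero_inflated_bernoulli = {
      stopifnot(p$pi >= 0, p$pi <= 1, p$prob >= 0, p$prob <= 1)
      q <- (1 - p$pi) * p$prob
      list(mean = q, sd = sqrt(q * (1 - q)))
    },
    point_mass = list(mean = p$value, sd = 0)
  )
}

#' Draw values from a resource distribution
#'
#' Seeded draws are reproducible through R's global RNG stream; callers
#' should `set.seed()` (or use [mc_config()]'s seed) for determinism. The
#' truncation policy keeps draws on the physically meaningful support:
#' scores in [0, 1] and densities non-negative.
#'
#' @param dist A [resource_distribution()].
#' @param n Number of draws.
#' @param truncation `"clip"` (censor at the support bounds; default),
#'   `"reject"` (resample until inside the bounds), or `"none"`.
#' @return Numeric vector of length `n`.
#' @export
sample_value <- function(dist, n = 1,
                         truncation = c("clip", "reject", "none")) {
  stopifnot(inherits(dist, "resource_distribution"))
  truncation <- match.arg(truncation)
  draw <- function(n) {
    p <- dist$params
    switch(dist$family,
      normal = rnorm(n, p$mean, p$sd),
      beta = rbeta(n, p$shape1, p$shape2),
      exponential = rexp(n, p$rate),
      negative_binomial = rnbinom(n, mu = p$mu, size = p$size),
      zero_inflated_poisson =
        ifelse(runif(n) < p$pi, 0, rpois(n, p$lambda)),
      zero_inflated_negative_binomial =
        ifelse(runif(n) < p$pi, 0, rnbinom(n, mu = p$mu, size = p$size)),
      zero_inflated_bernoulli =
        ifelse(runif(n) < p$pi, 0, rbinom(n, 1, p$prob)),
      point_mass = rep(p$value, n),
      stop("unknown family: ", dist$family, call. = FALSE)
    )
  }
  x <- draw(n)
  lo <- 0
  hi <- if (identical(dist$units, "score")) 1 else Inf
  if (truncation == "clip") {
    x <- pmin(pmax(x, lo), hi)
  } else if (truncation == "reject") {
    bad <- which(x < lo | x > hi)
    guard <- 0L
    while (length(bad)) {
      x[bad] <- draw(length(bad))
      bad <- bad[x[bad] < lo | x[bad] > hi]
      guard <- guard + 1L
      if (guard > 10000L) {
        stop("rejection sampling failed to find in-support draws",
             call. = FALSE)
      }
    }
  }
  x
}

#' Aggregate expert-survey scores into per-cell normal distributions
#'
#' Expert elicitation in this workflow scores each land-cover class on a
#' 5-level rating scale labelled 0.10 / 0.25 / 0.5 / 0.75 / 0.95. Scores are
#' aggregated across respondents with the sample mean and sample SD (n - 1
#' denominator) for each class x season x resource cell, yielding a normal
#' score distribution per cell.
#'
#' @param responses Data frame with columns `respondent_id`, `class_id`,
#'   `season`, `resource`, `score`.
#' @param check_levels If `TRUE` (default), reject scores outside the 5
#'   admissible levels.
#' @return Tibble with one row per class x season x resource:
#'   `n_respondents`, `mean`, `sd`, `family = "normal"`, `units = "score"`.
#'   Cells with fewer than 2 respondents are an error (the SD is undefined).
#' @export
aggregate_survey <- function(responses, check_levels = TRUE) {
  need <- c("respondent_id", "class_id", "season", "resource", "score")
  miss <- setdiff(need, names(responses))
  if (length(miss)) {
    stop("survey table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (check_levels &&
      !all(sapply(responses$score,
                  function(s) any(abs(s - SCORE_LEVELS) < 1e-9)))) {
    stop("survey scores must be one of ",
         paste(format(SCORE_LEVELS), collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(responses[, c("respondent_id", "class_id", "season",
                                  "resource")])
  if (any(dup)) {
    stop("duplicate respondent x class x season x resource rows",
         call. = FALSE)
  }
  out <- responses |>
    dplyr::group_by(.data$class_id, .data$season, .data$resource) |>
    dplyr::summarise(n_respondents = dplyr::n(),
                     mean = mean(.data$score),
                     sd = sd(.data$score),
                     .groups = "drop")
  if (any(out$n_respondents < 2)) {
    bad <- out[out$n_respondents < 2, ]
    stop("fewer than 2 respondents for: ",
         paste(bad$class_id, bad$season, bad$resource, sep = "/",
               collapse = "; "), call. = FALSE)
  }
  out$family <- "normal"
  out$units <- "score"
  out
}

#' Read and validate a classification-scheme agreement matrix
#'
#' An agreement matrix gives, for each class of the *target* scheme, the
#' proportions of its area mapped to each class of the *source* scheme (the
#' scheme the scores were elicited on). Rows must lie on the simplex.
#'
#' @param proportion Numeric matrix, rows = target classes, columns = source
#'   classes, with `dimnames`.
#' @param tol Tolerance for the row-sum-to-1 check.
#' @return The validated matrix, classed `agreement_matrix`.
#' @export
agreement_matrix <- function(proportion, tol = 1e-9) {
  stopifnot(is.matrix(proportion))
  if (any(proportion < 0) || any(proportion > 1)) {
    stop("agreement proportions must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(proportion)
  if (any(abs(rs - 1) > tol)) {
    stop("agreement-matrix rows must each sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  if (is.null(rownames(proportion)) || is.null(colnames(proportion))) {
    stop("agreement matrix needs row (target) and column (source) names",
         call. = FALSE)
  }
  structure(proportion, class = c("agreement_matrix", "matrix", "array"))
}

#' Translate per-class score distributions across classification schemes
#'
#' Each target-scheme class is a mosaic of source-scheme classes in the
#' proportions of the agreement matrix. Survey-based normal distributions
#' are translated by taking the proportion-weighted average of the source
#' means and — following the convention of averaging reported spreads — of
#' the source SDs. An alternative `"variance"` pooling mode combines the
#' mixture second moments instead (correct for a random-mosaic
#' interpretation); the SD-averaging rule is the default because it is the
#' convention the bundled reference tables were built with.
#'
#' @param source_dists Data frame with `class_id`, `mean`, `sd` for every
#'   source class that receives nonzero weight.
#' @param am An [agreement_matrix()] whose columns name source classes and
#'   rows name target classes.
#' @param pooling `"weighted_sd"` (default) or `"variance"`.
#' @return Tibble with `class_id` (target), `mean`, `sd`,
#'   `family = "normal"`.
#' @export
crosswalk_distributions <- function(source_dists, am,
                                    pooling = c("weighted_sd", "variance")) {
  pooling <- match.arg(pooling)
  am <- agreement_matrix(unclass(am))
  src_needed <- colnames(am)[colSums(am) > 0]
  miss <- setdiff(src_needed, as.character(source_dists$class_id))
  if (length(miss)) {
    stop("no source distribution for weighted classes: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  mu <- setNames(source_dists$mean, source_dists$class_id)[colnames(am)]
  sg <- setNames(source_dists$sd, source_dists$class_id)[colnames(am)]
  mu[is.na(mu)] <- 0  # zero-weight columns only, guarded above
  sg[is.na(sg)] <- 0
  t_mean <- as.vector(am %*% mu)
  t_sd <- if (pooling == "weighted_sd") {
    as.vector(am %*% sg)
  } else {
    # mixture variance: E[V] + V[E]
    second <- as.vector(am %*% (sg^2 + mu^2))
    sqrt(pmax(second - t_mean^2, 0))
  }
  tibble::tibble(class_id = rownames(am), mean = t_mean, sd = t_sd,
                 family = "normal")
}

#' Collapse per-crop seasonal values into a single cropland-class value
#'
#' Land-cover products with a single generic cropland class need one floral
#' value even though published per-crop scores distinguish dozens of crop
#' types. The per-crop values are combined as a weighted average using each
#' crop's average share of the cropland class, after dropping excluded
#' categories (e.g. grass/sod, whose acreage cannot be separated from
#' grass/hay cover) and renormalizing the remaining shares to 1.
#'
#' @param crop_values Data frame with `crop`, `mean` and optionally `sd`.
#' @param shares Named numeric vector of per-crop area shares (need not sum
#'   to 1; renormalized over included crops).
#' @param exclude Character vector of crop names to drop before weighting.
#' @return List with `mean` and `sd` (weighted mean of SDs; `NA` if no SDs).
#' @export
crop_weighted_value <- function(crop_values, shares, exclude = character()) {
  stopifnot(all(c("crop", "mean") %in% names(crop_values)))
  keep <- setdiff(intersect(crop_values$crop, names(shares)), exclude)
  if (!length(keep)) stop("no crops left after exclusion", call. = FALSE)
  w <- shares[keep]
  if (sum(w) <= 0) stop("total share of included crops is zero", call. = FALSE)
  w <- w / sum(w)
  v <- crop_values[match(keep, crop_values$crop), ]
  m <- sum(w * v$mean)
  s <- if ("sd" %in% names(v)) sum(w * v$sd) else NA_real_
  list(mean = m, sd = s, shares = w)
}
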