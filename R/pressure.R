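#' The ten human-pressure criteria
#'
#' Column names of the ten ordinal disturbance criteria scored 1
#' (minimum disturbance) to 5 (maximum disturbance) at every site:
#' land use, urban area, riparian vegetation, connectivity (barriers),
#' sediment load, hydrological regime, morphological condition,
#' artificial lentic water bodies, toxic/acidification levels, and
#' nutrient/organic loads.
#'
#' @return Character vector of length 10.
#' @export
pressure_criteria <- function() {
  c("land_use", "urban_area", "riparian_vegetation", "connectivity",
    "sediment_load", "hydrological_regime", "morphological_condition",
    "artificial_lentic_water_bodies", "toxic_acid_levels",
    "nutrient_organic_loads")
}

# extract and validate the 10-score matrix from a site table or a
# named vector of ten scores
pressure_scores <- function(profile) {
  crit <- pressure_criteria()
  if (is.data.frame(profile)) {
    missing_cols <- setdiff(crit, names(profile))
    if (length(missing_cols))
      stop("missing pressure criterion column(s): ",
           paste(missing_cols, collapse = ", "))
    m <- as.matrix(profile[, crit, drop = FALSE])
  } else {
    if (is.null(names(profile)))
      stop("a pressure profile must be a named vector or a data frame")
    missing_crit <- setdiff(crit, names(profile))
    if (length(missing_crit))
      stop("missing pressure criterion score(s): ",
           paste(missing_crit, collapse = ", "))
    m <- matrix(profile[crit], nrow = 1, dimnames = list(NULL, crit))
  }
  if (any(is.na(m)) || any(m %% 1 != 0) || any(m < 1) || any(m > 5))
    stop("pressure scores must be integers in 1..5")
  m
}

#' Total human pressure of a site
#'
#' Sum of the ten ordinal pressure scores; ranges from 10 (pristine on
#' every criterion) to 50 (maximal disturbance on every criterion).
#'
#' @param profile Either a named vector holding the ten criterion
#'   scores, or a site data frame with the ten criterion columns.
#' @return Integer vector (one value per site/row).
#' @examples
#' p <- setNames(rep(1, 10), pressure_criteria())
#' total_pressure(p)  # 10
#' @export
total_pressure <- function(profile) {
  as.integer(rowSums(pressure_scores(profile)))
}

#' Reference-condition classification
#'
#' A site is in reference (undisturbed or least-disturbed) condition
#' iff every one of its ten scores is 1 or 2, allowing at most a
#' single score of 3; any score of 4 or 5, or two or more 3s,
#' disqualifies it.
#'
#' @inheritParams total_pressure
#' @return Logical vector: `TRUE` for reference sites.
#' @examples
#' classify_reference(setNames(c(rep(1, 9), 3), pressure_criteria()))  # TRUE
#' @export
classify_reference <- function(profile) {
  m <- pressure_scores(profile)
  rowSums(m > 3) == 0 & rowSums(m == 3) <= 1
}

#' Quality classes along the total-pressure gradient
#'
#' Bins total human pressure (10..50) into the five ecological quality
#' classes High, Good, Moderate, Poor, Bad. Boundaries are the class
#' lower edges; the default is five equal-width bins over the
#' attainable range: High \[10, 18), Good \[18, 26), Moderate
#' \[26, 34), Poor \[34, 42), Bad \[42, 50\]. The mapping is monotone:
#' a larger total never maps to a better class.
#'
#' @param total Integer total pressure in \[10, 50\] (vectorised).
#' @param boundaries Increasing numeric vector of the four inner class
#'   lower edges (Good, Moderate, Poor, Bad).
#' @return Ordered factor with levels High < Good < Moderate < Poor <
#'   Bad.
#' @examples
#' assign_quality_class(c(10, 30, 50))
#' @export
assign_quality_class <- function(total, boundaries = c(18, 26, 34, 42)) {
  if (any(is.na(total)) || any(total < 10) || any(total > 50))
    stop("total pressure must be in [10, 50]")
  if (length(boundaries) != 4 || is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be four strictly increasing values")
  lv <- c("High", "Good", "Moderate", "Poor", "Bad")
  idx <- findInterval(total, boundaries) + 1L
  factor(lv[idx], levels = lv, ordered = TRUE)
}

#' Site classification report
#'
#' Applies scoring, reference classification and quality-class binning
#' to every site of a site table.
#'
#' @param sites Site data frame carrying the ten criterion columns.
#' @param boundaries Passed to [assign_quality_class()].
#' @return Data frame: `site_id`, `total_pressure`, `reference`,
#'   `quality_class`.
#' @export
classify_sites <- function(sites, boundaries = c(18, 26, 34, 42)) {
  total <- total_pressure(sites)
  data.frame(
    site_id = sites$site_id,
    total_pressure = total,
    reference = classify_reference(sites),
    quality_class = assign_quality_class(total, boundaries),
    stringsAsFactors = FALSE
  )
}
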