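#' Frequency of occurrence
#'
#' Proportion of the selected sites at which at least one of the
#' selected species is present (density > 0).
#'
#' @param table A [density_table()].
#' @param species Character vector of species names, or `"non_native"`
#'   / `"native"` / `"diadromous"` to select by origin; default all
#'   non-natives.
#' @param sites Character vector of site ids; default all sites.
#' @return A proportion in \[0, 1\].
#' @examples
#' sp <- data.frame(species = c("a", "b"),
#'                  origin = c("non_native", "native"))
#' tab <- density_table(c("s1", "s2"), sp, rbind(c(2, 0), c(0, 1)))
#' frequency_of_occurrence(tab)  # 0.5
#' @export
frequency_of_occurrence <- function(table, species = "non_native",
                                    sites = NULL) {
  stopifnot(inherits(table, "density_table"))
  sp <- resolve_species(table, species)
  if (is.null(sites)) sites <- table$sites
  if (!length(sites)) stop("empty site subset")
  unknown <- setdiff(sites, table$sites)
  if (length(unknown))
    stop("unknown site(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  sub <- table$density[match(sites, table$sites), sp, drop = FALSE]
  mean(rowSums(sub > 0) > 0)
}

resolve_species <- function(table, species) {
  if (length(species) == 1 &&
      species %in% c("non_native", "native", "diadromous")) {
    sp <- table$species$species[table$species$origin == species]
  } else {
    unknown <- setdiff(species, table$species$species)
    if (length(unknown))
      stop("unknown species: ", paste(unknown, collapse = ", "))
    sp <- species
  }
  if (!length(sp)) stop("empty species subset")
  sp
}

#' Non-native fraction of site species richness
#'
#' At each requested site, the number of non-native species present
#' (density > 0) divided by the number of all species present; defined
#' as 0 where no fish are present.
#'
#' @param table A [density_table()].
#' @param sites Site ids; default all.
#' @return Named numeric vector of proportions in \[0, 1\].
#' @export
nns_richness_fraction <- function(table, sites = NULL) {
  stopifnot(inherits(table, "density_table"))
  if (is.null(sites)) sites <- table$sites
  unknown <- setdiff(sites, table$sites)
  if (length(unknown))
    stop("unknown site(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  present <- table$density[match(sites, table$sites), , drop = FALSE] > 0
  nns <- table$species$origin == "non_native"
  n_all <- rowSums(present)
  n_nns <- rowSums(present[, nns, drop = FALSE])
  out <- ifelse(n_all == 0, 0, n_nns / n_all)
  names(out) <- sites
  out
}

#' Pool group means into a weighted grand mean
#'
#' Reconstructs a survey-wide mean from per-group (e.g. per river
#' type) means and group sizes: `sum(mean * n) / sum(n)`. This is the
#' arithmetic that links published per-type summary cells to the
#' survey-wide figures when raw data are unavailable; groups where the
#' quantity is structurally zero enter with mean 0 and their full n.
#'
#' @param means Numeric vector of group means.
#' @param n Integer vector of group sizes (> 0), same length.
#' @return The pooled mean.
#' @examples
#' pooled_weighted_mean(c(2, 0), c(10, 30))  # 0.5
#' @export
pooled_weighted_mean <- function(means, n) {
  if (!length(means)) stop("empty group list")
  if (length(means) != length(n)) stop("means and n differ in length")
  if (any(n <= 0)) stop("all group sizes must be > 0")
  sum(means * n) / sum(n)
}

#' Ordinal density classes
#'
#' Standardises a density by the species maximum over the analysed
#' dataset and bins the ratio into four ordinal classes:
#' 0 (absent), 1 (0-10\% of the maximum), 2 (10-50\%), 3 (> 50\%).
#' Boundary ratios fall to the lower class, so the four classes
#' partition \[0, 1\]. This transformation tames the many zeros of
#' riverine density matrices before Poisson modelling.
#'
#' @param density Numeric vector of densities, `0 <= density <=
#'   species_max`.
#' @param species_max The species' maximum density over the dataset
#'   (> 0).
#' @return Integer vector of classes in 0..3.
#' @examples
#' density_to_class(c(0, 0.8, 7), species_max = 10)  # 0 1 3
#' @export
density_to_class <- function(density, species_max) {
  if (length(species_max) != 1 || species_max <= 0)
    stop("species_max must be a single value > 0")
  if (any(density < 0)) stop("densities must be >= 0")
  if (any(density > species_max))
    stop("density exceeds species_max")
  ratio <- density / species_max
  ifelse(density == 0, 0L,
         ifelse(ratio <= 0.10, 1L, ifelse(ratio <= 0.50, 2L, 3L)))
}

#' Per-river-type invasibility summary
#'
#' Tabulates, per river type (and optionally per disturbance group),
#' the non-native frequency of occurrence, mean per-site non-native
#' richness fraction (in %), and mean and SD of summed non-native
#' density — the block structure of the survey's published summary.
#'
#' @param table A [density_table()].
#' @param sites Site data frame with `site_id` and `river_type` (and
#'   the ten pressure columns if `by_reference = TRUE`).
#' @param by_reference If `TRUE`, adds `undisturbed` / `disturbed`
#'   blocks using [classify_reference()].
#' @return Data frame with one row per river type x group.
#' @export
type_invasibility_summary <- function(table, sites, by_reference = FALSE) {
  stopifnot(inherits(table, "density_table"))
  if (!all(c("site_id", "river_type") %in% names(sites)))
    stop("sites must carry site_id and river_type")
  groups <- list(total = sites$site_id)
  if (by_reference) {
    ref <- classify_reference(sites)
    groups <- c(groups, list(undisturbed = sites$site_id[ref],
                             disturbed = sites$site_id[!ref]))
  }
  nns <- table$species$origin == "non_native"
  out <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    for (rt in unique(sites$river_type)) {
      sub <- intersect(ids, sites$site_id[sites$river_type == rt])
      if (!length(sub)) next
      idx <- match(sub, table$sites)
      nns_dens <- rowSums(table$density[idx, nns, drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        group = g, river_type = rt, n_sites = length(sub),
        nns_foc = if (any(nns))
          frequency_of_occurrence(table, "non_native", sub) else 0,
        nns_richness_pct = 100 * mean(nns_richness_fraction(table, sub)),
        nns_density_mean = mean(nns_dens),
        nns_density_sd = stats::sd(nns_dens),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
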