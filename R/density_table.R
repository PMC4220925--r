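#' Site x species density table
#'
#' Container for a site-by-species matrix of fish densities
#' (individuals per 100 m2) with a species origin map. The matrix
#' rows follow `site_ids`, columns follow `species$species`.
#'
#' @param site_ids Character vector of unique site identifiers.
#' @param species Data frame with columns `species` (unique labels)
#'   and `origin` (one of `"native"`, `"non_native"`, `"diadromous"`).
#' @param density Numeric matrix, sites x species, all values >= 0.
#' @return An object of class `density_table` with fields `sites`,
#'   `species`, `density`.
#' @export
density_table <- function(site_ids, species, density) {
  site_ids <- as.character(site_ids)
  if (anyDuplicated(site_ids)) stop("duplicated site ids")
  stopifnot(is.data.frame(species),
            all(c("species", "origin") %in% names(species)))
  if (anyDuplicated(species$species)) stop("duplicated species names")
  bad_origin <- setdiff(unique(species$origin),
                        c("native", "non_native", "diadromous"))
  if (length(bad_origin))
    stop("unknown species origin: ", paste(bad_origin, collapse = ", "))
  density <- as.matrix(density)
  if (nrow(density) != length(site_ids) || ncol(density) != nrow(species))
    stop("density matrix dimensions do not match sites/species")
  if (any(!is.finite(density)) || any(density < 0))
    stop("densities must be finite and >= 0")
  dimnames(density) <- list(site_ids, species$species)
  structure(list(sites = site_ids,
                 species = species[, c("species", "origin")],
                 density = density),
            class = "density_table")
}

#' @export
print.density_table <- function(x, ...) {
  cat(sprintf("density_table: %d sites x %d species (%d non-native)\n",
              length(x$sites), nrow(x$species),
              sum(x$species$origin == "non_native")))
  cat(sprintf("  occupied cells: %.1f%%\n", 100 * mean(x$density > 0)))
  invisible(x)
}

#' @export
dim.density_table <- function(x) dim(x$density)

#' Write / read a density table as long-format CSV
#'
#' The on-disk layout is long: one row per site x species cell with
#' columns `site_id`, `species`, `origin`, `density` (UTF-8, comma
#' separated, "." decimal, header row).
#'
#' @param x A `density_table`.
#' @param path File path.
#' @return `write_density_table` returns `path` invisibly;
#'   `read_density_table` returns a validated [density_table()].
#' @export
write_density_table <- function(x, path) {
  stopifnot(inherits(x, "density_table"))
  long <- data.frame(
    site_id = rep(x$sites, times = nrow(x$species)),
    species = rep(x$species$species, each = length(x$sites)),
    origin = rep(x$species$origin, each = length(x$sites)),
    density = as.vector(x$density),
    stringsAsFactors = FALSE
  )
  utils::write.csv(long, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_density_table
#' @export
read_density_table <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "species", "origin", "density")
  missing_cols <- setdiff(need, names(long))
  if (length(missing_cols))
    stop("density table missing columns: ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(long$density) | long$density < 0)
  if (length(bad))
    stop("negative or non-finite density at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  sites <- unique(long$site_id)
  sp <- unique(long[, c("species", "origin")])
  if (anyDuplicated(sp$species))
    stop("species listed with conflicting origins")
  dens <- matrix(0, length(sites), nrow(sp),
                 dimnames = list(sites, sp$species))
  dens[cbind(match(long$site_id, sites), match(long$species, sp$species))] <-
    long$density
  density_table(sites, sp, dens)
}
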