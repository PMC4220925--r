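#' River typology of continental Portugal
#'
#' Morpho-climatic characteristics (mean and SD) of the 12 river types
#' defined for continental Portugal under the EU Water Framework
#' Directive, together with the number of sites sampled in each type by
#' the national electrofishing survey this package's analyses are
#' designed around (sampling effort proportional to basin area;
#' 380 sites in total). These specifications parameterise the synthetic
#' survey generator.
#'
#' Types run along two gradients: north to south (decreasing altitude
#' and precipitation, increasing temperature) and west to east
#' (continentality). `M` are northern mountain trout streams; `N*` are
#' northern types split by drainage area and the Alto Douro region; `L`
#' is the littoral centre-west; `S*` are southern, mostly temporary
#' streams, with `S4` the small chalk streams of the Algarve.
#'
#' @return A data frame with one row per river type and columns
#'   `river_type`, `temperature_mean`, `temperature_sd` (deg C),
#'   `precipitation_mean`, `precipitation_sd` (mm),
#'   `altitude_mean`, `altitude_sd` (m),
#'   `drainage_area_mean`, `drainage_area_sd` (km2), `n_sites`.
#' @examples
#' rt <- river_type_specs()
#' sum(rt$n_sites)  # 380
#' @export
river_type_specs <- function() {
  data.frame(
    river_type = c("M", "N1<100", "N1>100", "N2", "N3", "N4",
                   "L", "S1<100", "S1>100", "S2", "S3", "S4"),
    temperature_mean   = c(11.0, 12.4, 12.6, 13.1, 13.0, 14.1,
                           14.8, 15.7, 15.8, 15.4, 15.6, 16.9),
    temperature_sd     = c(1.5, 1.3, 1.2, 1.0, 0.8, 0.7,
                           0.3, 0.9, 0.9, 0.3, 0.4, 0.5),
    precipitation_mean = c(1944, 1190, 1196, 596, 671, 1065,
                           941, 628, 587, 743, 730, 632),
    precipitation_sd   = c(379, 358, 374, 81, 134, 168,
                           118, 86, 84, 85, 118, 60),
    altitude_mean      = c(506, 413, 274, 300, 432, 280,
                           44, 183, 137, 175, 54, 54),
    altitude_sd        = c(300, 242, 205, 141, 160, 122,
                           44, 75, 68, 147, 46, 57),
    drainage_area_mean = c(24.8, 33, 549, 960, 32, 151,
                           180, 30, 439, 60, 388, 67),
    drainage_area_sd   = c(17, 23, 65, 1115, 23, 361,
                           671, 21, 579, 87, 1081, 89),
    n_sites            = c(28L, 60L, 68L, 20L, 28L, 16L,
                           33L, 26L, 33L, 22L, 37L, 9L),
    stringsAsFactors = FALSE
  )
}

# environmental variables carried by every simulated site
env_variable_names <- function() {
  c("temperature", "precipitation", "altitude", "drainage_area")
}

#' Species pool of the survey
#'
#' The fish species recorded by the survey with their origin class:
#' 10 non-native species plus representative native and diadromous
#' taxa of Portuguese rivers. Used as the default species pool of the
#' density simulator and to flag non-natives in community metrics.
#'
#' @return Data frame with columns `species` and
#'   `origin` (`"native"`, `"non_native"` or `"diadromous"`).
#' @export
default_species_pool <- function() {
  data.frame(
    species = c(
      # non-native
      "Lepomis gibbosus", "Gobio lozanoi", "Gambusia holbrooki",
      "Cyprinus carpio", "Carassius auratus", "Micropterus salmoides",
      "Herichthys facetum", "Ameiurus melas", "Sander lucioperca",
      "Alburnus alburnus",
      # native cyprinids and allies
      "Squalius alburnoides", "Squalius pyrenaicus", "Luciobarbus bocagei",
      "Pseudochondrostoma polylepis", "Cobitis paludica", "Salmo trutta",
      # diadromous
      "Anguilla anguilla", "Petromyzon marinus"
    ),
    origin = c(rep("non_native", 10), rep("native", 6), rep("diadromous", 2)),
    stringsAsFactors = FALSE
  )
}

#' Published per-river-type invasibility summary of the national survey
#'
#' Per-river-type summary statistics of non-native fish published for
#' the 380-site national survey: frequency of occurrence of any
#' non-native species and mean densities (individuals/100 m2) of the
#' three focal invaders, for the ten river types where non-natives
#' occurred. The two types without any non-native record (`M`, 28
#' sites; `S4`, 9 sites) contribute zeros when pooling over all 380
#' sites. The raw site-level data were never deposited; these cells are
#' the published aggregate and are used to reconstruct the survey-wide
#' pooled metrics.
#'
#' @return Data frame with one row per river type with occurrences and
#'   columns `river_type`, `n_sites`, `nns_foc`,
#'   `dens_lepomis_gibbosus`, `dens_gobio_lozanoi`,
#'   `dens_gambusia_holbrooki`.
#' @seealso [pooled_weighted_mean()] for the pooling arithmetic.
#' @export
survey_type_summary <- function() {
  data.frame(
    river_type = c("N1<100", "N1>100", "N2", "N3", "N4",
                   "L", "S1<100", "S1>100", "S2", "S3"),
    n_sites = c(60L, 68L, 20L, 28L, 16L, 33L, 26L, 33L, 22L, 37L),
    nns_foc = c(0.1, 0.4, 0.7, 0.07, 0.2, 0.5, 0.4, 0.7, 0.3, 0.5),
    dens_lepomis_gibbosus = c(0.1, 1.1, 0.6, 0.01, 0.3,
                              0.8, 2.3, 2.1, 0.06, 2.3),
    dens_gobio_lozanoi = c(2.2, 3.4, 0.6, 0.07, 0,
                           7.5, 0, 0, 0, 1.6),
    dens_gambusia_holbrooki = c(0, 0.03, 0, 0, 0.01,
                                0.7, 1.1, 2.7, 0.9, 1.1),
    stringsAsFactors = FALSE
  )
}

# per-type counts for the two types without non-native occurrences
survey_absent_types <- function() {
  data.frame(river_type = c("M", "S4"), n_sites = c(28L, 9L),
             stringsAsFactors = FALSE)
}
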