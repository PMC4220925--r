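#' Simulate a site table for the 12-type river survey
#'
#' Draws a synthetic site table with the statistical structure the
#' downstream analyses assume: per-type environmental variables from
#' the typology's means and SDs (independent truncated normals, so the
#' marginals match the typology; covariances are not emulated),
#' planar coordinates uniform on the unit square, ten ordinal human
#' pressure scores in 1..5 driven by a latent per-site disturbance
#' intensity, and water-chemistry pressure covariates that increase
#' with that intensity.
#'
#' The disturbance intensity u is drawn from a two-component Beta
#' mixture: with probability `ref_mix` a low-disturbance component
#' (default Beta(1, 15)), otherwise a disturbed component (default
#' Beta(5, 2.5)). Each of the ten scores is `1 + Binomial(4, u)`, so
#' scores co-vary within a site (a disturbance syndrome) and the
#' low-disturbance component classifies as reference under the
#' scoring rule in the large majority of draws, giving close to the
#' roughly even reference/disturbed split of the survey design.
#'
#' @param specs River-type specification data frame as returned by
#'   [river_type_specs()]; `n_sites` may be edited to scale the survey.
#' @param seed Integer seed; identical seeds give identical tables.
#' @param ref_mix Probability a site is drawn from the low-disturbance
#'   mixture component.
#' @param low_shape,high_shape Length-2 Beta shape parameters of the
#'   low- and high-disturbance components of the intensity mixture.
#' @return A data frame with one row per site: `site_id`, `river_type`,
#'   coordinates `x`, `y`, the four environmental variables
#'   (`temperature`, `precipitation`, `altitude`, `drainage_area`),
#'   the ten pressure scores (columns named as in
#'   [pressure_criteria()]), eight chemistry covariates (mg/L), and the
#'   latent `disturbance` intensity used to generate scores and
#'   chemistry (kept for diagnostics; not an observable of a real
#'   survey).
#' @examples
#' sites <- simulate_sites(seed = 1)
#' nrow(sites)  # 380
#' @export
simulate_sites <- function(specs = river_type_specs(), seed,
                           ref_mix = 0.48,
                           low_shape = c(1, 15), high_shape = c(5, 2.5)) {
  if (missing(seed)) stop("'seed' is required for a reproducible survey")
  validate_specs(specs)
  stopifnot(ref_mix >= 0, ref_mix <= 1)
  set.seed(as.integer(seed))

  n_total <- sum(specs$n_sites)
  river_type <- rep(specs$river_type, specs$n_sites)

  env <- list(
    temperature   = c(-273, Inf),
    precipitation = c(0, Inf),
    altitude      = c(0, Inf),
    drainage_area = c(1e-6, Inf)
  )
  site <- data.frame(
    site_id = sprintf("S%03d", seq_len(n_total)),
    river_type = river_type,
    x = stats::runif(n_total),
    y = stats::runif(n_total),
    stringsAsFactors = FALSE
  )
  for (v in names(env)) {
    mu <- rep(specs[[paste0(v, "_mean")]], specs$n_sites)
    sd <- rep(specs[[paste0(v, "_sd")]], specs$n_sites)
    site[[v]] <- rtruncnorm(n_total, mu, sd, env[[v]][1])
  }

  low <- stats::runif(n_total) < ref_mix
  u <- ifelse(low,
              stats::rbeta(n_total, low_shape[1], low_shape[2]),
              stats::rbeta(n_total, high_shape[1], high_shape[2]))
  for (crit in pressure_criteria()) {
    site[[crit]] <- 1L + stats::rbinom(n_total, 4L, u)
  }

  # chemistry: lognormal baselines climbing with disturbance intensity
  chem <- chemistry_model()
  for (i in seq_len(nrow(chem))) {
    site[[chem$name[i]]] <- exp(stats::rnorm(
      n_total, log(chem$base[i]) + chem$slope[i] * u, chem$noise_sd[i]))
  }
  site$n_total <- site$no2 + site$no3 + site$nh4
  site$disturbance <- u
  attr(site, "seed") <- as.integer(seed)
  site
}

chemistry_model <- function() {
  data.frame(
    name = c("bod5", "cod", "tss", "srp", "no2", "no3", "nh4"),
    base = c(1.5, 8, 5, 0.02, 0.01, 0.5, 0.05),
    slope = c(2.2, 2.0, 2.5, 2.5, 2.0, 2.0, 2.5),
    noise_sd = c(0.4, 0.4, 0.5, 0.5, 0.4, 0.5, 0.5),
    stringsAsFactors = FALSE
  )
}

chemistry_names <- function() c(chemistry_model()$name, "n_total")

validate_specs <- function(specs) {
  need <- c("river_type", "n_sites",
            paste0(rep(env_variable_names(), each = 2), c("_mean", "_sd")))
  missing_cols <- setdiff(need, names(specs))
  if (length(missing_cols))
    stop("river-type specs missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(specs$river_type))
    stop("duplicated river type in specs")
  sds <- unlist(specs[paste0(env_variable_names(), "_sd")])
  if (any(sds < 0)) stop("negative SD in river-type specs")
  if (any(specs$n_sites < 0)) stop("negative n_sites in river-type specs")
  invisible(specs)
}

# vectorised truncated-normal draw by rejection; sd = 0 degenerates to mean
rtruncnorm <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  out[sd == 0] <- mean[sd == 0]
  bad <- which(out < lower & sd > 0)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[out[bad] < lower]
    guard <- guard + 1L
    if (guard > 10000L) { # pathological mean far below bound
      out[bad] <- lower
      break
    }
  }
  out
}

#' Effect configuration for the density simulator
#'
#' Bundles the log-linear effect structure used by
#' [simulate_densities()]: named coefficient vectors on standardised
#' environmental variables, pressure variables (scores and chemistry)
#' and cubic trend-surface terms, an intercept on the log scale, and a
#' covariate-independent zero-inflation probability.
#'
#' Coefficients act on z-scored predictors (centred and scaled across
#' the supplied sites), so a coefficient is the change in log expected
#' density per SD of the variable.
#'
#' @param env,pressure,spatial Named numeric vectors of coefficients;
#'   names must be, respectively, environmental variable names,
#'   pressure score/chemistry names, and trend-surface term names
#'   (`x`, `y`, `xy`, `x2`, `y2`, `x2y`, `xy2`, `x3`, `y3`).
#' @param intercept Log expected density (per 100 m2) at predictor
#'   means; default `log(2)`.
#' @param zero_inflation Probability in \[0, 1\] that a site x species
#'   cell is forced to zero irrespective of covariates.
#' @param seed Optional integer seed used by [simulate_densities()].
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(env = numeric(0), pressure = numeric(0),
                          spatial = numeric(0), intercept = log(2),
                          zero_inflation = 0.3, seed = NULL) {
  check_named <- function(x, what) {
    if (length(x) && (is.null(names(x)) || any(names(x) == "")))
      stop(what, " coefficients must be a named numeric vector")
    x
  }
  if (zero_inflation < 0 || zero_inflation > 1)
    stop("zero_inflation must be in [0, 1]")
  structure(list(env = check_named(env, "env"),
                 pressure = check_named(pressure, "pressure"),
                 spatial = check_named(spatial, "spatial"),
                 intercept = intercept,
                 zero_inflation = zero_inflation,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "effect_config")
}

#' Simulate a site x species density table
#'
#' For each site and species, the expected density is
#' `lambda = exp(intercept + sum(beta * z))` over the configured
#' environmental, pressure and trend-surface terms (z-scored across
#' sites); the realised density is a Poisson draw (individuals per
#' 100 m2), masked to zero with probability `zero_inflation`
#' independently per cell. All species share the same effect structure;
#' differences between species in a realisation come from the
#' independent draws.
#'
#' @param sites Site table from [simulate_sites()] (or any table with
#'   the referenced columns plus `x`, `y`).
#' @param species Species pool data frame (`species`, `origin`);
#'   default [default_species_pool()].
#' @param config An [effect_config()]. Its `seed` (required here)
#'   makes the table reproducible.
#' @return A [density_table()] object.
#' @export
simulate_densities <- function(sites, species = default_species_pool(),
                               config = effect_config(seed = 1)) {
  stopifnot(inherits(config, "effect_config"))
  if (is.null(config$seed))
    stop("config$seed is required for a reproducible density table")
  set.seed(config$seed)

  n <- nrow(sites)
  eta <- rep(config$intercept, n)
  add_terms <- function(eta, coefs, table, what) {
    unknown <- setdiff(names(coefs), colnames(table))
    if (length(unknown))
      stop("unknown ", what, " variable(s) in coefficient map: ",
           paste(unknown, collapse = ", "))
    for (v in names(coefs)) {
      z <- table[[v]]
      s <- stats::sd(z)
      z <- if (is.na(s) || s == 0) rep(0, n) else (z - mean(z)) / s
      eta <- eta + coefs[[v]] * z
    }
    eta
  }
  eta <- add_terms(eta, config$env,
                   sites[, intersect(env_variable_names(), names(sites)),
                         drop = FALSE], "environmental")
  eta <- add_terms(eta, config$pressure,
                   sites[, intersect(c(pressure_criteria(), chemistry_names()),
                                     names(sites)), drop = FALSE], "pressure")
  if (length(config$spatial)) {
    sp <- build_spatial_terms(sites$x, sites$y)
    eta <- add_terms(eta, config$spatial, sp, "spatial")
  }

  lambda <- exp(eta)
  k <- nrow(species)
  dens <- matrix(stats::rpois(n * k, rep(lambda, k)), nrow = n, ncol = k)
  if (config$zero_inflation > 0) {
    mask <- matrix(stats::runif(n * k) < config$zero_inflation, n, k)
    dens[mask] <- 0
  }
  density_table(sites$site_id, species, dens)
}
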