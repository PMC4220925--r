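#' Transform predictors before modelling
#'
#' Applies the workflow's conventional normalising transformations:
#' `log(x + 1)` (natural log) for linear measurements and
#' `arcsin(sqrt(x))` for proportions; percentages are divided by 100
#' first.
#'
#' @param x Numeric vector.
#' @param kind `"log"` for measurements, `"arcsin_sqrt"` for
#'   proportions in \[0, 1\], `"arcsin_sqrt_pct"` for percentages in
#'   \[0, 100\].
#' @return Transformed vector.
#' @export
transform_predictor <- function(x, kind = c("log", "arcsin_sqrt",
                                            "arcsin_sqrt_pct")) {
  kind <- match.arg(kind)
  switch(kind,
         log = {
           if (any(x < 0)) stop("log(x + 1) needs x >= 0")
           log1p(x)
         },
         arcsin_sqrt = {
           if (any(x < 0 | x > 1)) stop("proportions must be in [0, 1]")
           asin(sqrt(x))
         },
         arcsin_sqrt_pct = {
           if (any(x < 0 | x > 100)) stop("percentages must be in [0, 100]")
           asin(sqrt(x / 100))
         })
}

#' Read and validate a site table
#'
#' Reads the pipeline's site CSV (UTF-8, comma separated, "." decimal,
#' header row) and validates it row by row: known river types, the ten
#' pressure scores in 1..5, non-negative chemistry. Violations are
#' reported with row and column.
#'
#' @param path CSV path.
#' @param types Admissible river type labels; default those of
#'   [river_type_specs()].
#' @return Validated site data frame.
#' @export
read_site_table <- function(path, types = river_type_specs()$river_type) {
  sites <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "river_type", "x", "y",
            env_variable_names(), pressure_criteria())
  missing_cols <- setdiff(need, names(sites))
  if (length(missing_cols))
    stop("site table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(sites$site_id)) stop("duplicated site_id")
  bad_type <- which(!sites$river_type %in% types)
  if (length(bad_type))
    stop("unknown river type at row(s): ",
         paste(utils::head(bad_type, 5), collapse = ", "))
  for (crit in pressure_criteria()) {
    v <- sites[[crit]]
    bad <- which(is.na(v) | v %% 1 != 0 | v < 1 | v > 5)
    if (length(bad))
      stop(sprintf("score outside 1..5 in column '%s' at row(s): %s",
                   crit, paste(utils::head(bad, 5), collapse = ", ")))
  }
  for (chem in intersect(chemistry_names(), names(sites))) {
    bad <- which(!is.na(sites[[chem]]) & sites[[chem]] < 0)
    if (length(bad))
      stop(sprintf("negative value in column '%s' at row(s): %s",
                   chem, paste(utils::head(bad, 5), collapse = ", ")))
  }
  sites
}

#' @rdname read_site_table
#' @param sites Site data frame to write.
#' @export
write_site_table <- function(sites, path) {
  utils::write.csv(sites, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Assemble the modelling frame for a survey
#'
#' Joins a site table with derived modelling columns: transformed
#' environmental and chemistry predictors (natural `log(x + 1)` on
#' precipitation, altitude, drainage area and chemistry;
#' temperature kept on its native scale), total pressure, reference
#' flag, quality class, the nine trend-surface terms, and per focal
#' species the occurrence (0/1) and ordinal density class of the
#' summed analysis.
#'
#' @param sites Validated site table.
#' @param dens A [density_table()] for the same sites.
#' @param focal Character vector of focal species names.
#' @return List with `data` (modelling frame) and `sets` (character
#'   vectors `E`, `P`, `S` of predictor column names).
#' @export
build_model_frame <- function(sites, dens, focal) {
  stopifnot(inherits(dens, "density_table"))
  if (!all(sites$site_id %in% dens$sites))
    stop("density table lacks sites present in the site table")
  d <- sites
  for (v in c("precipitation", "altitude", "drainage_area"))
    d[[paste0("log_", v)]] <- transform_predictor(sites[[v]], "log")
  chem <- intersect(chemistry_names(), names(sites))
  for (v in chem)
    d[[paste0("log_", v)]] <- transform_predictor(sites[[v]], "log")
  d$total_pressure <- total_pressure(sites)
  d$reference <- classify_reference(sites)
  d$quality_class <- assign_quality_class(d$total_pressure)
  sp_terms <- build_spatial_terms(sites$x, sites$y)
  names(sp_terms) <- paste0("sp_", names(sp_terms))
  d <- cbind(d, sp_terms)

  dmat <- dens$density[match(sites$site_id, dens$sites), , drop = FALSE]
  for (sp in focal) {
    if (!sp %in% colnames(dmat)) stop("focal species not in table: ", sp)
    col <- gsub("[^A-Za-z0-9]+", "_", tolower(sp))
    v <- dmat[, sp]
    d[[paste0("occ_", col)]] <- as.integer(v > 0)
    smax <- max(v)
    d[[paste0("class_", col)]] <-
      if (smax > 0) density_to_class(v, smax) else rep(0L, nrow(d))
  }
  sets <- list(
    E = c("temperature", "log_precipitation", "log_altitude",
          "log_drainage_area"),
    P = c(pressure_criteria(), paste0("log_", chem)),
    S = paste0("sp_", spatial_term_names())
  )
  list(data = d, sets = sets)
}

#' Run the full invasibility analysis
#'
#' Orchestrates the workflow end to end: obtain data (simulate with a
#' seed, or read the two CSVs) -> pressure scoring and reference
#' classification -> per-type community metrics -> group tests
#' (reference vs disturbed occurrence and density; river types with
#' total pressure as covariable; quality classes with PCA1 as
#' covariable) -> collinearity screening and per-set forward selection
#' -> eight-component deviance partition per focal species for
#' occurrence (binomial) and density class (Poisson). All stage
#' outputs are written as CSV under `out_dir`.
#'
#' @param config List. Either `simulation = list(seed = , ...)`
#'   (passed to [simulate_sites()] / [effect_config()]) or
#'   `site_table` and `density_table` paths. Optional: `focal`
#'   (species names; default the three most frequent non-natives),
#'   `boundaries` (quality-class edges), `spearman_threshold` (0.75),
#'   `vif_cap` (3), `out_dir`.
#' @return List of stage outputs (`classification`, `metrics`,
#'   `tests`, `partitions`, `files`, `notices`), invisibly writing the
#'   CSVs.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir %||% tempfile("fishinvade_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  notices <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  dat <- stage("data", {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      if (is.null(sim$seed)) stop("simulation config needs a seed")
      sites <- simulate_sites(seed = sim$seed,
                              specs = sim$specs %||% river_type_specs(),
                              ref_mix = sim$ref_mix %||% 0.48)
      cfg <- sim$effects %||% effect_config(
        env = c(temperature = 0.6, drainage_area = 0.6),
        pressure = c(toxic_acid_levels = -0.3, nutrient_organic_loads = 0.4),
        zero_inflation = 0.3, seed = sim$seed + 1L)
      if (is.null(cfg$seed)) cfg$seed <- sim$seed + 1L
      dens <- simulate_densities(sites, sim$species %||%
                                   default_species_pool(), cfg)
      list(sites = sites, dens = dens)
    } else if (!is.null(config$site_table) &&
               !is.null(config$density_table)) {
      list(sites = read_site_table(config$site_table),
           dens = read_density_table(config$density_table))
    } else stop("config needs either 'simulation' or both input paths")
  })
  sites <- dat$sites; dens <- dat$dens

  boundaries <- config$boundaries %||% c(18, 26, 34, 42)
  classification <- stage("classification",
                          classify_sites(sites, boundaries))
  metrics <- stage("metrics",
                   type_invasibility_summary(dens, sites,
                                             by_reference = TRUE))

  nns <- dens$species$species[dens$species$origin == "non_native"]
  dmat <- dens$density[match(sites$site_id, dens$sites), , drop = FALSE]
  nns_total <- rowSums(dmat[, nns, drop = FALSE])
  any_nns <- any(nns_total > 0)

  foc_by_sp <- colMeans(dmat[, nns, drop = FALSE] > 0)
  focal <- config$focal %||%
    names(sort(foc_by_sp, decreasing = TRUE))[seq_len(min(3, sum(foc_by_sp > 0)))]

  tests <- stage("tests", {
    ref <- classification$reference
    rows <- list()
    # a degenerate contrast (e.g. non-natives everywhere or nowhere)
    # invalidates a single test, not the run: record a notice instead
    add <- function(label, expr) {
      res <- tryCatch(expr, error = function(e) {
        notices <<- c(notices,
                      sprintf("test '%s' skipped: %s", label,
                              conditionMessage(e)))
        NULL
      })
      if (is.null(res)) return(invisible(NULL))
      df <- res$df
      rows[[length(rows) + 1L]] <<- data.frame(
        test = label, statistic = res$statistic,
        df1 = if (is.null(df)) NA_real_ else df[1],
        df2 = if (is.null(df)) NA_real_ else df[2],
        p_value = res$p_value, stringsAsFactors = FALSE)
    }
    if (any_nns) {
      add("occurrence reference vs disturbed (Z)",
          two_proportion_z(sum(nns_total[ref] > 0), sum(ref),
                           sum(nns_total[!ref] > 0), sum(!ref)))
      add("density reference vs disturbed (Mann-Whitney)",
          mann_whitney(nns_total[ref], nns_total[!ref]))
      add("density by river type | total pressure (rank ANCOVA)",
          rank_ancova(nns_total, sites$river_type,
                      classification$total_pressure))
      pca1 <- pca_first_axis(sites[, env_variable_names()])$scores
      qc <- droplevels(classification$quality_class)
      ok <- qc %in% names(which(table(qc) >= 2))
      if (nlevels(droplevels(qc[ok])) >= 2)
        add("density by quality class | PCA1 (rank ANCOVA)",
            rank_ancova(nns_total[ok], qc[ok], pca1[ok]))
    } else notices <<- c(notices, "no non-native occurrences: tests limited")
    if (length(rows)) do.call(rbind, rows) else
      data.frame(test = character(0), statistic = numeric(0),
                 df1 = numeric(0), df2 = numeric(0), p_value = numeric(0))
  })

  partitions <- list()
  if (any_nns && length(focal)) {
    mf <- stage("model frame", build_model_frame(sites, dens, focal))
    thr <- config$spearman_threshold %||% 0.75
    vcap <- config$vif_cap %||% 3
    sets <- mf$sets
    sets$E <- stage("screen E", spearman_screen(mf$data[sets$E], thr))
    sets$P <- stage("screen P", spearman_screen(mf$data[sets$P], thr))
    for (sp in focal) {
      col <- gsub("[^A-Za-z0-9]+", "_", tolower(sp))
      for (resp in c("occ", "class")) {
        rcol <- paste0(resp, "_", col)
        if (stats::var(mf$data[[rcol]]) == 0) {
          notices <- c(notices, sprintf("constant response %s: skipped", rcol))
          next
        }
        fam <- if (resp == "occ") "binomial_logit" else "poisson_log"
        partitions[[rcol]] <- stage(
          paste("partition", rcol),
          partition_selected(rcol, sets, mf$data, fam, vif_cap = vcap))
      }
    }
  } else {
    notices <- c(notices,
                 "no non-native occurrences: partition stage skipped")
  }

  files <- stage("write", {
    f <- list(
      classification = file.path(out_dir, "classification.csv"),
      metrics = file.path(out_dir, "type_metrics.csv"),
      tests = file.path(out_dir, "tests.csv"),
      partitions = file.path(out_dir, "partitions.csv"))
    utils::write.csv(classification, f$classification, row.names = FALSE)
    utils::write.csv(metrics, f$metrics, row.names = FALSE)
    utils::write.csv(tests, f$tests, row.names = FALSE)
    part_rows <- lapply(names(partitions), function(nm) {
      p <- partitions[[nm]]
      cbind(data.frame(response = nm, family = p$family, n = p$n),
            as.data.frame(as.list(100 * p$fractions)))
    })
    part_df <- if (length(part_rows)) do.call(rbind, part_rows) else
      data.frame(response = character(0))
    utils::write.csv(part_df, f$partitions, row.names = FALSE)
    f
  })

  structure(list(classification = classification, metrics = metrics,
                 tests = tests, partitions = partitions,
                 focal = focal, files = files, notices = notices,
                 out_dir = out_dir),
            class = "fishinvade_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fishinvade_run <- function(x, ...) {
  cat(sprintf("fishinvade run: %d sites, %d reference\n",
              nrow(x$classification), sum(x$classification$reference)))
  cat(sprintf("  focal species: %s\n", paste(x$focal, collapse = ", ")))
  cat(sprintf("  partitions fitted: %d; outputs in %s\n",
              length(x$partitions), x$out_dir))
  for (n in x$notices) cat("  note:", n, "\n")
  invisible(x)
}
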