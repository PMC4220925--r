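#' Cubic trend-surface descriptors
#'
#' Builds the nine spatial descriptors of a third-degree polynomial
#' trend surface from site coordinates: x, y, xy, x2, y2, x2y, xy2,
#' x3, y3, with x and y centred to zero mean first (centring reduces
#' collinearity between successive polynomial terms). Only relative
#' positions matter, so any planar projection is acceptable.
#'
#' @param x,y Numeric site coordinates (finite, same length).
#' @return Data frame with the 9 descriptor columns.
#' @examples
#' build_spatial_terms(c(-1, 1), c(0, 0))
#' @export
build_spatial_terms <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad))
    stop("missing/non-finite coordinate at site index: ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (!length(x)) stop("need at least one site")
  xc <- x - mean(x)
  yc <- y - mean(y)
  data.frame(x = xc, y = yc, xy = xc * yc,
             x2 = xc^2, y2 = yc^2,
             x2y = xc^2 * yc, xy2 = xc * yc^2,
             x3 = xc^3, y3 = yc^3)
}

spatial_term_names <- function() {
  c("x", "y", "xy", "x2", "y2", "x2y", "xy2", "x3", "y3")
}

#' Explained-deviance fraction
#'
#' `D = 1 - residual deviance / null deviance`, the GLM analogue of
#' R-squared used throughout the partitioning.
#'
#' @param fit A converged [fit_glm()] with positive null deviance.
#' @return The fraction (0 for an intercept-only fit).
#' @export
explained_fraction <- function(fit) {
  stopifnot(inherits(fit, "glm_fit"))
  if (!fit$converged) stop("fit did not converge")
  if (fit$null_deviance <= 0)
    stop("null deviance is zero (constant response)")
  1 - fit$residual_deviance / fit$null_deviance
}

#' Eight-component deviance partition
#'
#' Decomposes the explained deviance of a GLM response into pure and
#' shared contributions of three predictor sets — environmental (E),
#' human pressure (P) and spatial trend-surface (S) — by
#' inclusion-exclusion over the seven models E, P, S, E+P, E+S, P+S,
#' E+P+S (all with the same family and data):
#'
#' * `a` pure E = D(EPS) - D(PS)
#' * `b` pure P = D(EPS) - D(ES)
#' * `c` pure S = D(EPS) - D(EP)
#' * `g` three-way shared = D(E)+D(P)+D(S)-D(EP)-D(ES)-D(PS)+D(EPS)
#' * `d` shared E-P = D(E)+D(P)-D(EP)-g
#' * `e` shared E-S = D(E)+D(S)-D(ES)-g
#' * `f` shared P-S = D(P)+D(S)-D(PS)-g
#' * `h` unexplained = 1 - D(EPS)
#'
#' The eight fractions sum to 1 by construction. Shared components
#' may be negative (suppression); they are reported as computed, never
#' truncated, since clamping would break the sum-to-one identity. An
#' empty set contributes D = 0 and the partition degrades gracefully
#' to the two-set case.
#'
#' @param response Response column name.
#' @param sets Named list with character vectors `E`, `P`, `S` of
#'   predictor column names (disjoint; any may be empty).
#' @param data Data frame holding response and all predictors; rows
#'   with missing values in any used column are dropped listwise so
#'   the seven deviances are comparable.
#' @param family GLM family label (see [fit_glm()]).
#' @return Object of class `deviance_partition`: the eight `fractions`
#'   (a..h), the seven model `D` values, `n` sites used, `family`.
#' @export
partition_deviance <- function(response, sets, data,
                               family = "poisson_log") {
  stopifnot(all(c("E", "P", "S") %in% names(sets)))
  E <- unique(sets$E); P <- unique(sets$P); S <- unique(sets$S)
  if (length(intersect(E, P)) || length(intersect(E, S)) ||
      length(intersect(P, S)))
    stop("predictor sets must be disjoint")
  used <- unique(c(response, E, P, S))
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols))
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(data[, used, drop = FALSE])
  data <- data[keep, , drop = FALSE]

  models <- list(E = E, P = P, S = S,
                 EP = c(E, P), ES = c(E, S), PS = c(P, S),
                 EPS = c(E, P, S))
  D <- vapply(names(models), function(nm) {
    terms <- models[[nm]]
    if (!length(terms)) return(0)
    fit <- fit_glm(response, terms, data, family)
    if (!fit$converged) stop("sub-model did not converge: ", nm)
    explained_fraction(fit)
  }, numeric(1))

  g <- D["E"] + D["P"] + D["S"] - D["EP"] - D["ES"] - D["PS"] + D["EPS"]
  fr <- c(a = D["EPS"] - D["PS"],
          b = D["EPS"] - D["ES"],
          c = D["EPS"] - D["EP"],
          d = D["E"] + D["P"] - D["EP"] - g,
          e = D["E"] + D["S"] - D["ES"] - g,
          f = D["P"] + D["S"] - D["PS"] - g,
          g = g,
          h = 1 - D["EPS"])
  names(fr) <- c("a", "b", "c", "d", "e", "f", "g", "h")
  structure(list(fractions = fr, D = D, n = nrow(data),
                 family = family, response = response, sets = sets),
            class = "deviance_partition")
}

#' @export
print.deviance_partition <- function(x, ...) {
  lab <- c(a = "pure environment", b = "pure pressure", c = "pure spatial",
           d = "shared env-pressure", e = "shared env-spatial",
           f = "shared pressure-spatial", g = "three-way shared",
           h = "unexplained")
  cat(sprintf("deviance partition of '%s' [%s], n = %d\n",
              x$response, x$family, x$n))
  for (k in names(x$fractions)) {
    flag <- if (x$fractions[k] < 0) "  (negative: suppression)" else ""
    cat(sprintf("  %-24s %6.1f%%%s\n", lab[k], 100 * x$fractions[k], flag))
  }
  invisible(x)
}

#' Partition with per-set forward selection
#'
#' The workflow's standard route to a partition: each of the three
#' candidate sets is first reduced by VIF-capped forward AIC selection
#' against the response ([forward_select()]), and the partition is
#' computed over the selected subsets ("minimal adequate" models). Set
#' `select = FALSE` to partition over the full candidate sets.
#'
#' @inheritParams partition_deviance
#' @param select Forward-select within each set first? Default `TRUE`.
#' @param vif_cap VIF cap for selection.
#' @return A `deviance_partition` (with a `selection` attribute
#'   holding the three traces when `select = TRUE`).
#' @export
partition_selected <- function(response, sets, data,
                               family = "poisson_log",
                               select = TRUE, vif_cap = 3) {
  selection <- NULL
  if (select) {
    selection <- lapply(sets, function(cand)
      forward_select(cand, response, data, family, vif_cap))
    sets <- lapply(selection, `[[`, "terms")
  }
  out <- partition_deviance(response, sets, data, family)
  attr(out, "selection") <- selection
  out
}
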