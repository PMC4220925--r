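glm_families <- function() {
  c("binomial_logit", "poisson_log", "quasibinomial_logit", "quasipoisson_log")
}

resolve_family <- function(family) {
  family <- match.arg(family, glm_families())
  switch(family,
         binomial_logit = stats::binomial("logit"),
         poisson_log = stats::poisson("log"),
         quasibinomial_logit = stats::quasibinomial("logit"),
         quasipoisson_log = stats::quasipoisson("log"))
}

is_quasi <- function(family) grepl("^quasi", family)

#' Fit a GLM for occurrence or density-class responses
#'
#' Maximum-likelihood GLM fit (iteratively reweighted least squares,
#' via [stats::glm()]) for the workflow's two response types:
#' presence/absence under `binomial_logit` and ordinal density classes
#' treated as counts under `poisson_log`. Quasi-likelihood variants
#' estimate a dispersion parameter by Pearson chi-square over residual
#' degrees of freedom and report a quasi-AIC (`-2 * loglik / phi +
#' 2 * k` using the corresponding likelihood family).
#'
#' @param response Name of the response column.
#' @param terms Character vector of predictor column names (may be
#'   empty: intercept-only model).
#' @param data Data frame holding response and predictors; no missing
#'   values in the used columns.
#' @param family One of `"binomial_logit"`, `"poisson_log"`,
#'   `"quasibinomial_logit"`, `"quasipoisson_log"`.
#' @param qaic_dispersion Optional fixed dispersion used for the
#'   quasi-AIC (e.g. from the largest candidate model during
#'   selection); default: the model's own Pearson estimate.
#' @return An object of class `glm_fit`: `spec` (family, response,
#'   terms), `coefficients`, `null_deviance`, `residual_deviance`,
#'   `aic`, `dispersion`, `converged`, plus the underlying `model`.
#' @export
fit_glm <- function(response, terms, data, family = "poisson_log",
                    qaic_dispersion = NULL) {
  family <- match.arg(family, glm_families())
  used <- c(response, terms)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols))
    stop("column(s) not in data: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(terms)) stop("duplicated terms")
  if (any(vapply(data[used], function(v) any(is.na(v)), logical(1))))
    stop("missing values in used columns")
  y <- data[[response]]
  if (grepl("binomial", family) && !all(y %in% c(0, 1)))
    stop("binomial family needs a 0/1 response")
  if (grepl("poisson", family) && (any(y < 0) || any(y %% 1 != 0)))
    stop("poisson family needs non-negative integer response")

  rhs <- if (length(terms))
    paste(sprintf("`%s`", terms), collapse = " + ") else "1"
  fml <- stats::as.formula(paste(sprintf("`%s`", response), "~", rhs))
  fit <- suppressWarnings(stats::glm(fml, data = data,
                                     family = resolve_family(family),
                                     control = stats::glm.control(
                                       epsilon = 1e-8, maxit = 100)))
  df_res <- fit$df.residual
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  dispersion <- if (df_res > 0) pearson / df_res else NA_real_
  aic <- fit$aic
  if (is_quasi(family)) {
    # quasi fits carry no likelihood; recompute under the parent family
    ll_fit <- suppressWarnings(stats::glm(
      fml, data = data,
      family = resolve_family(sub("^quasi", "", family))))
    phi <- if (!is.null(qaic_dispersion)) qaic_dispersion else dispersion
    k <- length(stats::coef(ll_fit)) + 1 # +1 for the dispersion itself
    aic <- -2 * as.numeric(stats::logLik(ll_fit)) / phi + 2 * k
  }
  structure(list(
    spec = list(family = family, response = response, terms = terms),
    coefficients = stats::coef(fit),
    null_deviance = fit$null.deviance,
    residual_deviance = fit$deviance,
    aic = aic,
    dispersion = dispersion,
    converged = fit$converged,
    df_residual = df_res,
    model = fit
  ), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("glm_fit [%s] %s ~ %s\n", x$spec$family, x$spec$response,
              if (length(x$spec$terms))
                paste(x$spec$terms, collapse = " + ") else "1"))
  cat(sprintf("  deviance %.3f / null %.3f (D = %.3f), AIC %.2f, dispersion %.3f\n",
              x$residual_deviance, x$null_deviance,
              1 - x$residual_deviance / x$null_deviance, x$aic, x$dispersion))
  invisible(x)
}

#' Overdispersion check
#'
#' Estimates the dispersion parameter as the Pearson chi-square
#' statistic over residual degrees of freedom and flags fits where it
#' exceeds 1, in which case the quasi-likelihood variant of the family
#' should be used.
#'
#' @param fit A [fit_glm()] result with positive residual df.
#' @return List with `dispersion` and `needs_quasi`.
#' @export
check_dispersion <- function(fit) {
  stopifnot(inherits(fit, "glm_fit"))
  if (!fit$converged) stop("fit did not converge")
  if (fit$df_residual <= 0) stop("zero residual degrees of freedom")
  list(dispersion = fit$dispersion, needs_quasi = fit$dispersion > 1)
}

#' Variance inflation factor
#'
#' `1 / (1 - R^2)` of one column regressed (ordinary least squares)
#' on the remaining columns of a design matrix. Perfect collinearity
#' yields `Inf`.
#'
#' @param design Data frame or matrix of predictor columns (>= 2).
#' @param term Column name to assess.
#' @return The VIF (>= 1).
#' @export
vif <- function(design, term) {
  design <- as.data.frame(design)
  if (ncol(design) < 2) stop("need at least 2 terms")
  if (!term %in% names(design)) stop("term not in design: ", term)
  y <- design[[term]]
  x <- as.matrix(design[setdiff(names(design), term)])
  fit <- stats::lm.fit(cbind(1, x), y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(Inf)
  rss <- sum(fit$residuals^2)
  r2 <- 1 - rss / tss
  if (r2 >= 1 - 1e-12) return(Inf)
  1 / (1 - r2)
}

max_vif <- function(design) {
  if (ncol(design) < 2) return(1)
  max(vapply(colnames(design), function(tm) vif(design, tm), numeric(1)))
}

#' Forward AIC selection under a VIF cap
#'
#' Starting from the intercept-only model, repeatedly adds the
#' candidate predictor giving the lowest AIC among those whose
#' addition keeps every VIF of the design at or below `vif_cap`;
#' stops when no admissible addition lowers the AIC. AIC ties are
#' broken by the larger single-term deviance reduction, then by
#' lexicographic name. For quasi families the selection criterion is
#' the quasi-AIC computed with a common dispersion taken from the
#' full candidate model.
#'
#' @param candidates Character vector of candidate predictor names
#'   (already screened for gross collinearity and transformed).
#' @param response Response column name.
#' @param data Data frame.
#' @param family GLM family label (see [fit_glm()]).
#' @param vif_cap Largest admissible VIF; default 3.
#' @return List with `fit` (the selected [fit_glm()]) and `trace`
#'   (data frame: step, term added, AIC before/after, deviance
#'   reduction, max VIF after).
#' @export
forward_select <- function(candidates, response, data,
                           family = "poisson_log", vif_cap = 3) {
  qaic_phi <- NULL
  if (is_quasi(family) && length(candidates)) {
    full <- fit_glm(response, candidates, data, family)
    qaic_phi <- max(full$dispersion, 1e-8)
  }
  refit <- function(terms) fit_glm(response, terms, data, family,
                                   qaic_dispersion = qaic_phi)
  current <- refit(character(0))
  selected <- character(0)
  remaining <- unique(candidates)
  trace <- list()
  while (length(remaining)) {
    best <- NULL
    for (cand in sort(remaining)) {
      design <- data[, c(selected, cand), drop = FALSE]
      if (length(selected) && max_vif(design) > vif_cap) next
      fit <- refit(c(selected, cand))
      if (!fit$converged) next
      dev_red <- current$residual_deviance - fit$residual_deviance
      if (is.null(best) ||
          fit$aic < best$fit$aic - 1e-9 ||
          (abs(fit$aic - best$fit$aic) <= 1e-9 && dev_red > best$dev_red)) {
        best <- list(term = cand, fit = fit, dev_red = dev_red,
                     max_vif = max_vif(design))
      }
    }
    if (is.null(best) || best$fit$aic >= current$aic) break
    trace[[length(trace) + 1L]] <- data.frame(
      step = length(trace) + 1L, term = best$term,
      aic_before = current$aic, aic_after = best$fit$aic,
      deviance_reduction = best$dev_red, max_vif = best$max_vif,
      stringsAsFactors = FALSE)
    selected <- c(selected, best$term)
    current <- best$fit
    remaining <- setdiff(remaining, best$term)
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(0), term = character(0),
               aic_before = numeric(0), aic_after = numeric(0),
               deviance_reduction = numeric(0), max_vif = numeric(0))
  list(fit = current, trace = trace, terms = selected)
}
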