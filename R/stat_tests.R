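test_result <- function(statistic, p_value, method, df = NULL) {
  structure(list(statistic = statistic, df = df,
                 p_value = p_value, method = method),
            class = "fishinvade_test")
}

#' @export
print.fishinvade_test <- function(x, ...) {
  dfs <- if (is.null(x$df)) "" else
    sprintf(" (df = %s)", paste(signif(x$df, 4), collapse = ", "))
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g\n",
              x$method, x$statistic, dfs, x$p_value))
  invisible(x)
}

#' Rank-transformation analysis of covariance
#'
#' Nonparametric ANCOVA in the rank-transform style: response and
#' covariate are replaced by their midranks and an ordinary linear
#' ANCOVA (`rank(y) ~ group + rank(cov)`) is fitted; the F statistic
#' for the group factor, adjusted for the covariate, is reported with
#' (g - 1, n - g - 1) degrees of freedom. Because only ranks enter,
#' the test is invariant under strictly monotone transformations of
#' response and covariate.
#'
#' A covariate with no variation is dropped (the test then reduces to
#' a one-way ANOVA on ranks, with n - g denominator df).
#'
#' @param response Numeric response per site.
#' @param group Factor (or coercible) with >= 2 levels, each with
#'   >= 2 observations.
#' @param covariate Numeric covariate per site.
#' @return A test result with `statistic` (F), `df` (numerator,
#'   denominator), `p_value`.
#' @export
rank_ancova <- function(response, group, covariate) {
  group <- droplevels(as.factor(group))
  n <- length(response)
  stopifnot(length(group) == n, length(covariate) == n)
  if (any(is.na(response)) || any(is.na(covariate)) || any(is.na(group)))
    stop("missing values are not supported")
  g <- nlevels(group)
  if (g < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("every group needs >= 2 observations")
  ry <- rank(response)
  if (stats::var(ry) == 0)
    stop("response is constant after ranking; F undefined")
  rc <- rank(covariate)
  has_cov <- stats::var(rc) > 0

  full <- if (has_cov) stats::lm(ry ~ group + rc) else stats::lm(ry ~ group)
  reduced <- if (has_cov) stats::lm(ry ~ rc) else stats::lm(ry ~ 1)
  rss_full <- sum(stats::resid(full)^2)
  rss_red <- sum(stats::resid(reduced)^2)
  df1 <- g - 1
  df2 <- n - g - as.integer(has_cov)
  f <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  test_result(f, stats::pf(f, df1, df2, lower.tail = FALSE),
              "rank-transformation ANCOVA", df = c(df1, df2))
}

#' Mann-Whitney U test
#'
#' U statistic for the first sample with midrank tie handling, normal
#' approximation with tie-corrected variance, and an exact mode.
#' `U` counts pairs (a, b) with a > b (ties counting 1/2), so
#' `U(a, b) + U(b, a) = n1 * n2`.
#'
#' The exact two-sided p-value is
#' `P(|U - n1 n2 / 2| >= |u_obs - n1 n2 / 2|)` under random rank
#' assignment: computed by the classical count recurrence when there
#' are no ties, and by full enumeration of the `choose(n1 + n2, n1)`
#' group assignments when there are (feasible for small samples only).
#'
#' @param a,b Numeric samples.
#' @param exact `TRUE`/`FALSE`, or `NULL` (default) to use the exact
#'   mode when `length(a) + length(b) <= 12`.
#' @return A test result with `statistic` (U of sample `a`) and
#'   `p_value`; the normal-approximation Z is attached as `z`.
#' @export
mann_whitney <- function(a, b, exact = NULL) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  z <- if (sig2 > 0) (u - mu) / sqrt(sig2) else 0
  if (is.null(exact)) exact <- N <= 12
  if (exact) {
    p <- if (anyDuplicated(c(a, b))) mw_exact_enum(a, b, u, mu)
         else mw_exact_counts(n1, n2, u, mu)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  res <- test_result(u, min(p, 1),
                     paste0("Mann-Whitney U",
                            if (exact) " (exact)" else " (normal approx.)"))
  res$z <- z
  res
}

# exact U distribution without ties, via the subset rank-sum DP:
# dp[k, s] = number of k-subsets of ranks 1..N summing to s
mw_exact_counts <- function(n1, n2, u_obs, mu) {
  N <- n1 + n2
  smax <- sum((N - n1 + 1):N)
  dp <- matrix(0, n1 + 1, smax + 1)
  dp[1, 1] <- 1
  for (el in seq_len(N)) {
    for (k in min(el, n1):1) {
      dp[k + 1, (el + 1):(smax + 1)] <-
        dp[k + 1, (el + 1):(smax + 1)] + dp[k, 1:(smax + 1 - el)]
    }
  }
  counts <- dp[n1 + 1, ]
  us <- (0:smax) - n1 * (n1 + 1) / 2 # U = ranksum - n1(n1+1)/2
  pr <- counts / sum(counts)
  sum(pr[abs(us - mu) >= abs(u_obs - mu) - 1e-9])
}

# tie-safe exact p by enumerating group assignments of the pooled values
mw_exact_enum <- function(a, b, u_obs, mu) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Two-proportion Z test
#'
#' Tests equality of two binomial proportions with the pooled-variance
#' Z statistic: `Z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with
#' pooled `p = (k1 + k2)/(n1 + n2)`; two-sided p from the standard
#' normal.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return A test result with `statistic` (Z) and `p_value`.
#' @examples
#' two_proportion_z(33, 182, 91, 198)
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p_pool <- (k1 + k2) / (n1 + n2)
  if (p_pool <= 0 || p_pool >= 1)
    stop("pooled proportion is 0 or 1; Z undefined")
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z <- (k1 / n1 - k2 / n2) / se
  test_result(z, 2 * stats::pnorm(-abs(z)), "two-proportion Z test")
}

#' Spearman collinearity screen
#'
#' Iteratively removes variables involved in strong rank correlations:
#' while any retained pair has `|rho| > threshold` with p < 0.05
#' (asymptotic Spearman test), the lowest-priority variable among the
#' offending pairs is dropped. The returned set has no offending pair
#' left. Priorities encode the analyst's judgement of ecological
#' relevance; by default, column order (earlier = keep).
#'
#' @param data Data frame or matrix of numeric candidate variables
#'   (>= 3 rows).
#' @param threshold Absolute rank-correlation threshold in (0, 1);
#'   default 0.75.
#' @param priorities Character vector of column names, highest
#'   priority first; default `colnames(data)`.
#' @return Character vector of retained variable names (in original
#'   column order).
#' @export
spearman_screen <- function(data, threshold = 0.75,
                            priorities = colnames(data)) {
  data <- as.data.frame(data)
  if (nrow(data) < 3) stop("need at least 3 observations")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (!setequal(priorities, colnames(data)))
    stop("priorities must be a permutation of the column names")
  keep <- colnames(data)
  repeat {
    if (length(keep) < 2) break
    offenders <- character(0)
    worst_rank <- -Inf
    for (i in seq_len(length(keep) - 1)) {
      for (j in (i + 1):length(keep)) {
        ct <- suppressWarnings(stats::cor.test(
          data[[keep[i]]], data[[keep[j]]],
          method = "spearman", exact = FALSE))
        if (is.na(ct$estimate)) next
        if (abs(ct$estimate) > threshold && ct$p.value < 0.05) {
          pr <- match(c(keep[i], keep[j]), priorities)
          loser <- c(keep[i], keep[j])[which.max(pr)]
          if (max(pr) > worst_rank) {
            worst_rank <- max(pr)
            offenders <- loser
          }
        }
      }
    }
    if (!length(offenders)) break
    keep <- setdiff(keep, offenders)
  }
  intersect(colnames(data), keep)
}

#' First principal component of standardised variables
#'
#' Extracts the dominant gradient of a variable matrix: variables are
#' centred and scaled to unit variance (correlation-scale PCA, since
#' environmental variables carry incommensurate units), and the first
#' eigenvector is returned with its explained-variance fraction and
#' per-site scores. The sign is fixed so the loading of largest
#' magnitude is positive.
#'
#' @param data Data frame or matrix (>= 3 rows, >= 2 numeric columns,
#'   no missing values).
#' @return List with `loadings` (unit norm), `variance_fraction`,
#'   `scores`.
#' @export
pca_first_axis <- function(data) {
  x <- as.matrix(as.data.frame(data))
  if (ncol(x) < 2) stop("need at least 2 variables")
  if (nrow(x) < 3) stop("need at least 3 observations")
  if (any(is.na(x))) stop("missing values are not supported")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance variable(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  load <- pc$rotation[, 1]
  scores <- pc$x[, 1]
  if (load[which.max(abs(load))] < 0) {
    load <- -load
    scores <- -scores
  }
  list(loadings = load,
       variance_fraction = pc$sdev[1]^2 / sum(pc$sdev^2),
       scores = scores)
}
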