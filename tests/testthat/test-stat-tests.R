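test_that("rank ANCOVA reduces to ANOVA on ranks when the covariate is flat", {
  set.seed(1)
  y <- rnorm(30)
  g <- rep(letters[1:3], each = 10)
  res <- rank_ancova(y, g, covariate = rep(1, 30))
  a <- anova(lm(rank(y) ~ factor(g)))
  expect_equal(res$statistic, a$`F value`[1], tolerance = 1e-12)
  expect_equal(res$df, c(2, 27))
})

test_that("rank ANCOVA matches the normal-equations oracle on a worked set", {
  y <- c(3.1, 2.7, 5.5, 4.2, 8.8, 7.3, 6.1, 9.4, 1.2, 2.2, 4.9, 6.6)
  g <- rep(c("a", "b", "c"), each = 4)
  cv <- c(10, 12, 9, 14, 20, 18, 22, 25, 5, 7, 11, 13)
  res <- rank_ancova(y, g, cv)
  orc <- rank_ancova_oracle(y, g, cv)
  expect_equal(res$statistic, orc$f, tolerance = 1e-10)
  expect_equal(res$df, orc$df)
})

test_that("rank ANCOVA is invariant under monotone transforms", {
  set.seed(2)
  y <- rexp(36)
  g <- rep(1:3, each = 12)
  cv <- runif(36)
  base <- rank_ancova(y, g, cv)
  tr <- rank_ancova(log(y + 1), g, exp(3 * cv))
  expect_equal(tr$statistic, base$statistic, tolerance = 1e-12)
  expect_equal(tr$p_value, base$p_value, tolerance = 1e-12)
})

test_that("rank ANCOVA input validation", {
  expect_error(rank_ancova(rep(1, 10), rep(1:2, 5), rnorm(10)), "constant")
  expect_error(rank_ancova(rnorm(3), c(1, 2, 2), rnorm(3)), ">= 2")
})

test_that("Mann-Whitney U statistic behaves at the boundaries", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  x <- c(1.5, 2.5, 9)
  expect_equal(mann_whitney(x, x)$statistic, length(x)^2 / 2)
  # U_a + U_b = n1 n2, with and without ties
  set.seed(3)
  for (i in 1:10) {
    a <- sample(1:6, 5, replace = TRUE)
    b <- sample(1:6, 7, replace = TRUE)
    expect_equal(mann_whitney(a, b, exact = FALSE)$statistic +
                   mann_whitney(b, a, exact = FALSE)$statistic,
                 length(a) * length(b))
  }
})

test_that("exact Mann-Whitney matches brute-force enumeration", {
  set.seed(4)
  # no ties: recurrence path against the subset-enumeration oracle
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(4)
    expect_equal(mann_whitney(a, b)$p_value, mw_enum_oracle(a, b),
                 tolerance = 1e-12)
  }
  # ties: enumeration path in the implementation, same oracle
  a <- c(1, 2, 2, 5); b <- c(2, 3, 3, 7)
  expect_equal(mann_whitney(a, b)$p_value, mw_enum_oracle(a, b),
               tolerance = 1e-12)
  # large-sample mode agrees with wilcox.test's normal approximation
  set.seed(5)
  x <- rnorm(30); y <- rnorm(25, 0.4)
  mine <- mann_whitney(x, y, exact = FALSE)
  wt <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(mine$statistic, unname(wt$statistic))
  expect_equal(mine$p_value, wt$p.value, tolerance = 1e-10)
})

test_that("two-proportion Z test: nulls, antisymmetry, survey headline", {
  r0 <- two_proportion_z(1, 2, 2, 4)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  r1 <- two_proportion_z(10, 50, 20, 60)
  r2 <- two_proportion_z(20, 60, 10, 50)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  # occurrence 0.18 of 182 undisturbed vs 0.46 of 198 disturbed
  head <- two_proportion_z(round(0.18 * 182), 182, round(0.46 * 198), 198)
  expect_lt(head$p_value, 0.001)
  expect_error(two_proportion_z(0, 10, 0, 10), "undefined")
  # cross-check against chi-square: Z^2 == X^2 without correction
  pt <- suppressWarnings(prop.test(c(10, 20), c(50, 60), correct = FALSE))
  expect_equal(r1$statistic^2, unname(pt$statistic), tolerance = 1e-10)
})

test_that("Spearman screen drops the lower-priority of correlated pairs", {
  set.seed(6)
  n <- 80
  a <- rnorm(n)
  d <- data.frame(a = a, b = a + rnorm(n, sd = 0.05), c = rnorm(n))
  expect_equal(spearman_screen(d), c("a", "c"))
  # duplicated variable: one copy retained
  d2 <- data.frame(a = a, a_copy = a, c = rnorm(n))
  expect_equal(spearman_screen(d2), c("a", "c"))
  # priorities reversed: the copy wins
  expect_equal(spearman_screen(d2, priorities = c("a_copy", "c", "a")),
               c("a_copy", "c"))
  # all weakly correlated: everything kept
  d3 <- as.data.frame(matrix(rnorm(n * 4), n))
  expect_equal(spearman_screen(d3), names(d3))
  expect_error(spearman_screen(d[1:2, ]), "3 observations")
})

test_that("first PCA axis matches an eigendecomposition oracle", {
  set.seed(7)
  x <- matrix(rnorm(50 * 5), 50, 5) %*% matrix(rnorm(25), 5, 5)
  colnames(x) <- paste0("v", 1:5)
  res <- pca_first_axis(x)
  ei <- eigen(cor(x))
  expect_equal(res$variance_fraction, ei$values[1] / sum(ei$values),
               tolerance = 1e-12)
  v <- ei$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  expect_equal(unname(res$loadings), v, tolerance = 1e-10)
  expect_equal(sum(res$loadings^2), 1, tolerance = 1e-12)
})

test_that("PCA axis handles degenerate and rescaled input", {
  z <- rnorm(20)
  two <- data.frame(p = z, q = 2 * z + 5)
  res <- pca_first_axis(two)
  expect_equal(res$variance_fraction, 1, tolerance = 1e-12)
  expect_equal(abs(unname(res$loadings)), rep(1 / sqrt(2), 2),
               tolerance = 1e-12)
  # scores invariant (up to sign) under affine rescaling of a column
  set.seed(8)
  x <- as.data.frame(matrix(rnorm(40 * 3), 40))
  s1 <- pca_first_axis(x)$scores
  x$V2 <- 100 * x$V2 - 7
  s2 <- pca_first_axis(x)$scores
  expect_lt(min(sum((s1 - s2)^2), sum((s1 + s2)^2)), 1e-16 * sum(s1^2) + 1e-12)
  expect_error(pca_first_axis(data.frame(a = rep(1, 5), b = rnorm(5))),
               "zero-variance.*a")
})
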