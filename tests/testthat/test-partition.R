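test_that("trend-surface descriptors are centred and complete", {
  one <- build_spatial_terms(0.7, 0.3)
  expect_equal(ncol(one), 9)
  expect_true(all(one == 0))
  two <- build_spatial_terms(c(-1, 1), c(0, 0))
  expect_equal(two$x, c(-1, 1))
  expect_equal(two$x2, c(1, 1))
  expect_true(all(two[, c("y", "xy", "y2", "x2y", "xy2", "y3")] == 0))
  expect_equal(two$x3, c(-1, 1))
  set.seed(20)
  many <- build_spatial_terms(runif(100), runif(100))
  expect_equal(names(many),
               c("x", "y", "xy", "x2", "y2", "x2y", "xy2", "x3", "y3"))
  expect_lt(abs(mean(many$x)), 1e-12)
  expect_lt(abs(mean(many$y)), 1e-12)
  expect_error(build_spatial_terms(c(1, NA), c(0, 0)), "site index")
})

test_that("explained fraction arithmetic", {
  fit <- structure(list(null_deviance = 120, residual_deviance = 30,
                        converged = TRUE), class = "glm_fit")
  expect_equal(explained_fraction(fit), 0.75)
  fit$null_deviance <- 0
  expect_error(explained_fraction(fit), "constant response")
})

test_that("the eight fractions always sum to one", {
  set.seed(21)
  for (i in 1:5) {
    n <- 150
    d <- data.frame(e1 = rnorm(n), e2 = rnorm(n), p1 = rnorm(n),
                    s1 = rnorm(n))
    d$y <- rpois(n, exp(0.1 + 0.4 * d$e1 + 0.3 * d$p1))
    pt <- partition_deviance("y", list(E = c("e1", "e2"), P = "p1",
                                       S = "s1"), d, "poisson_log")
    expect_equal(sum(pt$fractions), 1, tolerance = 1e-10)
  }
})

test_that("permuting set labels permutes the pure and pairwise fractions", {
  set.seed(22)
  n <- 200
  d <- data.frame(u = rnorm(n), v = rnorm(n), w = rnorm(n))
  d$y <- rpois(n, exp(0.2 + 0.5 * d$u + 0.2 * d$v - 0.3 * d$w))
  p1 <- partition_deviance("y", list(E = "u", P = "v", S = "w"), d,
                           "poisson_log")
  p2 <- partition_deviance("y", list(E = "v", P = "w", S = "u"), d,
                           "poisson_log")
  f1 <- p1$fractions; f2 <- p2$fractions
  # E,P,S -> (v,w,u): pure(v) was b, now a; shared g and h unchanged
  expect_equal(unname(f2["a"]), unname(f1["b"]), tolerance = 1e-12)
  expect_equal(unname(f2["b"]), unname(f1["c"]), tolerance = 1e-12)
  expect_equal(unname(f2["c"]), unname(f1["a"]), tolerance = 1e-12)
  expect_equal(unname(f2["d"]), unname(f1["f"]), tolerance = 1e-12)
  expect_equal(unname(f2["e"]), unname(f1["d"]), tolerance = 1e-12)
  expect_equal(unname(f2["f"]), unname(f1["e"]), tolerance = 1e-12)
  expect_equal(unname(f2["g"]), unname(f1["g"]), tolerance = 1e-12)
  expect_equal(unname(f2["h"]), unname(f1["h"]), tolerance = 1e-12)
})

test_that("an empty spatial set reduces to the two-set partition", {
  set.seed(23)
  n <- 150
  d <- data.frame(e1 = rnorm(n), p1 = rnorm(n))
  d$y <- rpois(n, exp(0.2 + 0.5 * d$e1 + 0.3 * d$p1))
  pt <- partition_deviance("y", list(E = "e1", P = "p1", S = character(0)),
                           d, "poisson_log")
  f <- pt$fractions
  expect_equal(unname(f[c("c", "e", "f", "g")]), rep(0, 4),
               tolerance = 1e-12)
  expect_equal(unname(f["a"]), pt$D[["EP"]] - pt$D[["P"]],
               tolerance = 1e-12)
  expect_equal(unname(f["b"]), pt$D[["EP"]] - pt$D[["E"]],
               tolerance = 1e-12)
  expect_equal(unname(f["d"]),
               pt$D[["E"]] + pt$D[["P"]] - pt$D[["EP"]],
               tolerance = 1e-12)
})

test_that("null response leaves everything unexplained", {
  set.seed(24)
  fr <- replicate(10, {
    n <- 200
    d <- data.frame(e1 = rnorm(n), p1 = rnorm(n), s1 = rnorm(n))
    d$y <- rpois(n, 2)
    partition_deviance("y", list(E = "e1", P = "p1", S = "s1"), d,
                       "poisson_log")$fractions
  })
  means <- rowMeans(fr)
  expect_true(all(abs(means[c("a", "b", "c", "d", "e", "f", "g")]) < 0.02))
  expect_gt(means["h"], 0.95)
})

test_that("Gaussian-limit partition equals the R^2 inclusion-exclusion oracle", {
  set.seed(25)
  n <- 200
  E <- matrix(rnorm(n * 2), n); P <- matrix(rnorm(n * 2), n)
  S <- matrix(rnorm(n), n)
  y <- 0.6 * E[, 1] + 0.4 * P[, 1] + 0.2 * S[, 1] + rnorm(n)
  d <- data.frame(E1 = E[, 1], E2 = E[, 2], P1 = P[, 1], P2 = P[, 2],
                  S1 = S[, 1], y = y)
  # identity-link Gaussian via lm deviances = residual sums of squares
  D <- function(terms) {
    if (!length(terms)) return(0)
    f <- lm(reformulate(terms, "y"), d)
    1 - sum(resid(f)^2) / sum((y - mean(y))^2)
  }
  sets <- list(E = c("E1", "E2"), P = c("P1", "P2"), S = "S1")
  Dv <- c(E = D(sets$E), P = D(sets$P), S = D(sets$S),
          EP = D(c(sets$E, sets$P)), ES = D(c(sets$E, sets$S)),
          PS = D(c(sets$P, sets$S)), EPS = D(unlist(sets)))
  g <- Dv["E"] + Dv["P"] + Dv["S"] - Dv["EP"] - Dv["ES"] - Dv["PS"] + Dv["EPS"]
  mine <- c(a = Dv[["EPS"]] - Dv[["PS"]], b = Dv[["EPS"]] - Dv[["ES"]],
            c = Dv[["EPS"]] - Dv[["EP"]],
            d = Dv[["E"]] + Dv[["P"]] - Dv[["EP"]] - g[[1]],
            e = Dv[["E"]] + Dv[["S"]] - Dv[["ES"]] - g[[1]],
            f = Dv[["P"]] + Dv[["S"]] - Dv[["PS"]] - g[[1]],
            g = g[[1]], h = 1 - Dv[["EPS"]])
  orc <- r2_partition_oracle(y, E, P, S)
  expect_equal(unname(mine), unname(orc), tolerance = 1e-8)
})

test_that("partition recovers a pure-environment signal in replicates", {
  set.seed(26)
  wins <- 0L
  reps <- 8L
  for (r in seq_len(reps)) {
    n <- 400
    d <- data.frame(e1 = rnorm(n), e2 = rnorm(n),
                    p1 = rnorm(n), s1 = rnorm(n))
    d$y <- rpois(n, exp(0.2 + 0.5 * d$e1 + 0.3 * d$e2))
    f <- partition_deviance("y", list(E = c("e1", "e2"), P = "p1",
                                      S = "s1"), d, "poisson_log")$fractions
    if (f[["a"]] > f[["b"]] && f[["a"]] > f[["c"]]) wins <- wins + 1L
  }
  expect_gte(wins, reps - 1L)
})

test_that("partition rejects overlapping sets and unknown columns", {
  d <- data.frame(a = rnorm(20), y = rpois(20, 2))
  expect_error(partition_deviance("y", list(E = "a", P = "a",
                                            S = character(0)), d),
               "disjoint")
  expect_error(partition_deviance("y", list(E = "zz", P = character(0),
                                            S = character(0)), d),
               "not in data")
})
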