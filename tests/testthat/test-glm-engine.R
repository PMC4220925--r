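test_that("Poisson intercept-only fit recovers the sample mean", {
  set.seed(10)
  d <- data.frame(y = rpois(50, 3))
  fit <- fit_glm("y", character(0), d, "poisson_log")
  expect_equal(unname(exp(fit$coefficients[1])), mean(d$y),
               tolerance = 1e-8)
  expect_equal(explained_fraction(fit), 0, tolerance = 1e-12)
})

test_that("saturated Poisson model has zero residual deviance", {
  d <- data.frame(y = c(1L, 4L, 2L, 7L),
                  g = factor(1:4))
  # one indicator per observation via the factor
  fit <- suppressWarnings(stats::glm(y ~ g, poisson(), data = d))
  expect_lt(fit$deviance, 1e-8)
})

test_that("binomial null deviance matches the closed form", {
  k <- 13; n <- 40
  d <- data.frame(y = c(rep(1L, k), rep(0L, n - k)))
  fit <- fit_glm("y", character(0), d, "binomial_logit")
  closed <- -2 * (k * log(k / n) + (n - k) * log(1 - k / n))
  expect_equal(fit$null_deviance, closed, tolerance = 1e-10)
  expect_equal(fit$residual_deviance, closed, tolerance = 1e-10)
})

test_that("fit_glm agrees with a Newton-Raphson oracle on a fixed dataset", {
  set.seed(11)
  n <- 30
  d <- data.frame(x1 = rnorm(n), x2 = runif(n))
  d$y <- rpois(n, exp(0.3 + 0.5 * d$x1 - 0.7 * d$x2))
  fit <- fit_glm("y", c("x1", "x2"), d, "poisson_log")
  orc <- nr_glm_oracle(as.matrix(d[, c("x1", "x2")]), d$y, "poisson_log")
  expect_equal(unname(fit$coefficients), unname(orc$coefficients),
               tolerance = 1e-6)
  expect_equal(fit$residual_deviance, orc$deviance, tolerance = 1e-6)

  d$z <- rbinom(n, 1, plogis(-0.2 + 0.8 * d$x1))
  fitb <- fit_glm("z", "x1", d, "binomial_logit")
  orcb <- nr_glm_oracle(matrix(d$x1), d$z, "binomial_logit")
  expect_equal(unname(fitb$coefficients), unname(orcb$coefficients),
               tolerance = 1e-6)
  expect_equal(fitb$residual_deviance, orcb$deviance, tolerance = 1e-6)
})

test_that("fit_glm validates input", {
  d <- data.frame(y = c(0L, 1L, 2L), x = 1:3)
  expect_error(fit_glm("y", "nope", d), "not in data")
  expect_error(fit_glm("y", "x", d, "binomial_logit"), "0/1")
  d$bad <- c(0.5, 1, 2)
  expect_error(fit_glm("bad", "x", d, "poisson_log"), "integer")
  d$x[1] <- NA
  expect_error(fit_glm("y", "x", d, "poisson_log"), "missing")
})

test_that("dispersion estimate is calibrated and flags overdispersion", {
  # arithmetic: Pearson 50 on 100 df -> 0.5, no quasi needed
  fit <- list(dispersion = 0.5, df_residual = 100, converged = TRUE)
  class(fit) <- "glm_fit"
  res <- check_dispersion(fit)
  expect_equal(res$dispersion, 0.5)
  expect_false(res$needs_quasi)
  # equidispersed Poisson: estimate within [0.9, 1.1] at n = 2000
  set.seed(12)
  d <- data.frame(x = rnorm(2000))
  d$y <- rpois(2000, exp(0.5 + 0.4 * d$x))
  disp <- check_dispersion(fit_glm("y", "x", d, "poisson_log"))
  expect_gt(disp$dispersion, 0.9)
  expect_lt(disp$dispersion, 1.1)
  # strongly overdispersed counts are flagged
  d$y2 <- rnbinom(2000, mu = exp(0.5 + 0.4 * d$x), size = 0.8)
  disp2 <- check_dispersion(fit_glm("y2", "x", d, "poisson_log"))
  expect_true(disp2$needs_quasi)
})

test_that("VIF matches its definition", {
  set.seed(13)
  n <- 400
  # orthogonalised pair: VIF 1
  a <- rnorm(n); b <- resid(lm(rnorm(n) ~ a))
  d <- data.frame(a = a, b = b)
  expect_equal(vif(d, "a"), 1, tolerance = 1e-10)
  # construct R^2 = 0.5 exactly: b2 = a + noise with matched variance
  noise <- resid(lm(rnorm(n) ~ a))
  noise <- noise * sd(a) / sd(noise)
  a_c <- a - mean(a)
  d2 <- data.frame(a = a, b2 = a_c + noise)
  expect_equal(vif(d2, "b2"), 2, tolerance = 1e-6)
  # duplicated predictor: infinite
  d3 <- data.frame(a = a, a2 = a)
  expect_equal(vif(d3, "a"), Inf)
})

test_that("forward selection finds a true predictor first, shuns duplicates", {
  set.seed(14)
  n <- 400
  d <- as.data.frame(matrix(rnorm(n * 6), n))
  names(d) <- c("true1", paste0("noise", 1:5))
  d$z_dup <- d$true1          # exact copy: AIC tie broken by name,
  d$y <- rpois(n, exp(0.2 + 0.8 * d$true1)) # then blocked by its VIF
  sel <- forward_select(c(names(d)[1:6], "z_dup"), "y", d, "poisson_log")
  expect_equal(sel$trace$term[1], "true1")
  expect_false("z_dup" %in% sel$terms)
  # residual deviance non-increasing along the accepted path
  expect_true(all(sel$trace$deviance_reduction >= -1e-9))
  expect_true(all(sel$trace$aic_after < sel$trace$aic_before))
  expect_true(all(sel$trace$max_vif <= 3))
})

test_that("noise terms admitted by AIC explain almost nothing", {
  # AIC forward selection accepts a spurious term whenever the best of
  # k chi-square(1) deviance reductions exceeds 2, so with many noise
  # candidates the null model is often *not* returned; the guarantee
  # worth having is that what gets in carries next to no deviance
  set.seed(15)
  frac <- replicate(30, {
    n <- 150
    d <- as.data.frame(matrix(rnorm(n * 8), n))
    d$y <- rpois(n, exp(0.3))
    explained_fraction(forward_select(names(d)[1:8], "y", d,
                                      "poisson_log")$fit)
  })
  expect_true(all(frac < 0.10))
  expect_lt(mean(frac), 0.05)
})

test_that("empty candidate list returns the intercept-only fit", {
  d <- data.frame(y = rpois(20, 2))
  sel <- forward_select(character(0), "y", d, "poisson_log")
  expect_equal(length(sel$terms), 0)
  expect_equal(nrow(sel$trace), 0)
  expect_equal(explained_fraction(sel$fit), 0, tolerance = 1e-12)
})
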