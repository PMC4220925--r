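# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths (and stats::glm) so that agreement is
# evidence, not tautology.

# Newton-Raphson GLM fit from the score equations, for poisson-log and
# binomial-logit with canonical links (so Fisher scoring == NR).
nr_glm_oracle <- function(X, y, family = c("poisson_log", "binomial_logit"),
                          tol = 1e-12, maxit = 200) {
  family <- match.arg(family)
  X <- as.matrix(cbind(1, X))
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- if (family == "poisson_log") exp(eta) else 1 / (1 + exp(-eta))
    w <- if (family == "poisson_log") mu else mu * (1 - mu)
    score <- crossprod(X, y - mu)
    info <- crossprod(X * w, X)
    step <- solve(info, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- if (family == "poisson_log") exp(eta) else 1 / (1 + exp(-eta))
  dev <- if (family == "poisson_log") {
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  } else {
    -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  list(coefficients = beta, deviance = dev)
}

# R^2 of an OLS fit via explicit projection (QR on the design).
r2_oracle <- function(X, y) {
  X <- as.matrix(cbind(1, X))
  fit <- qr.fitted(qr(X), y)
  1 - sum((y - fit)^2) / sum((y - mean(y))^2)
}

# classical variance partitioning by inclusion-exclusion over R^2,
# mirroring the eight-component layout
r2_partition_oracle <- function(y, E, P, S) {
  D <- list(E = r2_oracle(E, y), P = r2_oracle(P, y), S = r2_oracle(S, y),
            EP = r2_oracle(cbind(E, P), y), ES = r2_oracle(cbind(E, S), y),
            PS = r2_oracle(cbind(P, S), y),
            EPS = r2_oracle(cbind(E, P, S), y))
  g <- D$E + D$P + D$S - D$EP - D$ES - D$PS + D$EPS
  c(a = D$EPS - D$PS, b = D$EPS - D$ES, c = D$EPS - D$EP,
    d = D$E + D$P - D$EP - g, e = D$E + D$S - D$ES - g,
    f = D$P + D$S - D$PS - g, g = g, h = 1 - D$EPS)
}

# brute-force two-sided exact Mann-Whitney p by enumerating all
# group-1 index subsets of the pooled sample
mw_enum_oracle <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  mu <- n1 * length(b) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- combn(length(pooled), n1,
              FUN = function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# least-squares ANCOVA-on-ranks F for the group factor via explicit
# normal equations (no lm), for the fixed worked datasets
rank_ancova_oracle <- function(y, grp, cov) {
  ry <- rank(y); rc <- rank(cov)
  grp <- as.factor(grp)
  G <- model.matrix(~ grp)  # intercept + g-1 indicators
  Xf <- cbind(G, rc)
  Xr <- cbind(1, rc)
  rss <- function(X) {
    b <- solve(crossprod(X), crossprod(X, ry))
    sum((ry - X %*% b)^2)
  }
  g <- nlevels(grp); n <- length(y)
  f <- ((rss(Xr) - rss(Xf)) / (g - 1)) / (rss(Xf) / (n - g - 1))
  list(f = f, df = c(g - 1, n - g - 1))
}

named_scores <- function(values) stats::setNames(values, pressure_criteria())

# small fixture survey used by several suites
make_fixture_survey <- function(seed = 42, n_per_type = 5) {
  specs <- river_type_specs()
  specs$n_sites <- rep(n_per_type, nrow(specs))
  sites <- simulate_sites(specs, seed = seed)
  cfg <- effect_config(env = c(temperature = 0.8, drainage_area = 0.5),
                       zero_inflation = 0.3, seed = seed + 1)
  dens <- simulate_densities(sites, default_species_pool(), cfg)
  list(sites = sites, dens = dens)
}
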