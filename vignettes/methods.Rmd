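---
title: "Methods: pressure scoring, invasibility metrics and deviance partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pressure scoring, invasibility metrics and deviance partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishinvade)
```

## The scientific problem

Non-native fish (NNS) are among the main biological pressures on
Mediterranean-climate rivers. Two classes of explanation compete for
their success: the natural environmental template (warm, lowland,
large-drainage rivers suit warm-water invaders) and the "human
activity" hypothesis (degraded sites are easier to invade and receive
more propagules). Because human pressure concentrates in exactly the
lowland river types that are also environmentally favourable, the two
explanations are confounded in raw comparisons. This package
implements a workflow that separates them: ordinal pressure scoring
and reference classification, community invasibility metrics,
covariate-adjusted nonparametric tests, and a GLM-based partition of
explained deviance into pure and shared components of three predictor
sets — environmental (E), human pressure (P) and spatial trend (S).

## Pressure scoring and reference conditions

Ten criteria (`pressure_criteria()`) are scored 1 (minimal
disturbance) to 5 (maximal). **Total human pressure** is their sum,
in [10, 50]. A site is in **reference condition** iff every score is
1 or 2 with at most a single 3 (`classify_reference()`); the rule is
monotone — raising any score can only remove, never confer, reference
status — and the test suite asserts this by perturbation.

Five **quality classes** (High, Good, Moderate, Poor, Bad) bin the
total. The source methodology prescribes an approach, not numeric
boundaries, so the package defaults to five equal-width bins over the
attainable range — High [10, 18), Good [18, 26), Moderate [26, 34),
Poor [34, 42), Bad [42, 50] — and exposes the inner edges as a
parameter of `assign_quality_class()`. Under these defaults every
possible reference profile (total at most 21) falls in High or Good,
verified by exhaustive enumeration. The boundaries are a reporting
convention, not an inferential quantity: the tests and ANCOVAs that
use the classes only require the binning to be monotone.

Water-chemistry variables (BOD5, COD, TSS, SRP, NO2, NO3, NH4, total
inorganic N; mg/L) complement the evaluation as model covariates in
the pressure set; they are deliberately *not* folded into the total
score.

## Community metrics

* `frequency_of_occurrence()` — share of selected sites where any
  selected species has density > 0.
* `nns_richness_fraction()` — per site, non-native species present
  over all species present (0 where no fish).
* `density_to_class()` — densities standardised by the species
  maximum over the analysed dataset and binned into 0 (absent),
  1 (0–10%], 2 (10–50%], 3 (> 50%). Boundary ratios fall to the lower
  class so the four classes partition [0, 1]. The species maximum is
  taken over all sites of the river types where the species occurs.
* `pooled_weighted_mean()` — Σ(mean·n)/Σn. The survey-wide published
  figures are reconstructed with it from the per-type cells in
  `survey_type_summary()`, with the two types lacking any NNS
  contributing zeros at their full site counts (28 and 9 of the 380).
  Per-type cells are printed to 1–2 digits, so reconstructions carry
  that rounding: the pooled mean for *Gobio lozanoi* lands at 1.80
  against a printed survey-wide 1.79, and the pooled occurrence at
  0.335 against a printed "33% of sites" (the summary table's own
  "total" column shows 0.30, which is not consistent with the
  n-weighted mean of its own cells — we report the reconstruction).
  Whether the per-type NNS richness percentage is a per-site average
  or a pooled ratio is not fully specified in the source; the package
  averages the per-site fraction, the reading consistent with its
  site-level definition.

Biomass follows the density pattern in this system and is redundant;
no biomass metrics are computed.

## The nonparametric toolbox

**Rank-transformation ANCOVA** (`rank_ancova()`): response and
covariate replaced by midranks, ordinary ANCOVA
(`rank(y) ~ group + rank(cov)`) fitted by least squares, F for the
group factor with (g−1, n−g−1) df. Of the two classical flavours of
nonparametric ANCOVA we implement the rank-transform (Conover–Iman)
one — the literal reading of "ANCOVA on ranks"; Quade's
residual-on-ranks variant is a documented possible extension, not a
default. Both the response and the covariate are ranked (the sources
leave the covariate's treatment unstated; ranking both keeps the
procedure fully invariant under monotone transforms of either, which
the suite asserts). A constant covariate is dropped, reducing the
test to one-way ANOVA on ranks with n−g denominator df.

**Mann–Whitney** (`mann_whitney()`): U of the first sample from
midranks; normal approximation with tie-corrected variance; exact
mode (default for n1+n2 ≤ 12) via the classical subset rank-sum
recurrence when there are no ties, or full enumeration of group
assignments under ties. The exact two-sided p is the probability mass
of |U − n1n2/2| at least as extreme as observed.

**Two-proportion Z** (`two_proportion_z()`): pooled-variance Z,
two-sided; degenerate pooled proportions (0 or 1) raise an error
rather than returning a meaningless statistic.

All tests are two-sided (sidedness is never stated in the source
methodology; two-sided is the conservative convention), and no
multiple-testing correction is applied across the battery, matching
the source analysis.

**Collinearity screen** (`spearman_screen()`): iteratively drops the
lowest-priority variable of any pair with |ρ| > 0.75 and p < 0.05
(asymptotic t approximation — appropriate at survey sample sizes).
Priorities default to column order; they are the deterministic
surrogate for the expert "ecological relevance" judgement of the
original screening, and the screen records exactly which variables
survive.

**PCA1** (`pca_first_axis()`): correlation-scale PCA (environmental
variables have incommensurate units), sign fixed so the largest
loading is positive; used as the environmental covariable in the
quality-class ANCOVA.

## GLMs and forward selection

Occurrence is modelled binomial with logit link; ordinal density
classes are modelled Poisson with log link. Treating a bounded
0–3 class as a count is statistically unusual but is the stated
procedure of the methodology this workflow operationalises; it is a
pragmatic response to the extreme zero-inflation of riverine density
matrices, and the package documents rather than hides it. Predictors
are transformed before modelling (`transform_predictor()`): natural
`log(x+1)` for linear measurements, `arcsin(sqrt(x))` for proportions
(percentages divided by 100 first).

Fitting is by iteratively reweighted least squares (`stats::glm`,
convergence: relative deviance change < 1e-8, ≤ 100 iterations); the
suite verifies coefficients and deviance against an independent
Newton–Raphson oracle to 6 significant figures. Overdispersion is
estimated as Pearson χ²/df (`check_dispersion()`); above 1 the
quasi-family path applies, with selection under a quasi-AIC computed
at the full candidate model's dispersion. (In the motivating survey
all dispersions stayed below 1, so the quasi path exists for
completeness.)

`forward_select()` starts from the intercept-only model and
repeatedly adds the candidate with the lowest AIC among those whose
addition keeps every VIF ≤ 3 (`vif()` is 1/(1−R²) of a term on its
co-predictors), stopping when no admissible addition lowers AIC. AIC
ties break by larger single-term deviance reduction, then by name. A
property worth stating plainly: AIC forward selection is *not* a
null-model filter — with k pure-noise candidates, at least one enters
whenever the best of k χ²(1) deviance reductions exceeds 2, which for
k = 10 happens in roughly four runs of five. What the procedure does
guarantee, and what the unit suite asserts, is that spurious
admissions carry almost no deviance.

## Spatial descriptors and the deviance partition

`build_spatial_terms()` centres x and y to zero mean and returns the
nine cubic trend-surface terms x, y, xy, x², y², x²y, xy², x³, y³ —
the polynomial surface absorbs broad-scale spatial autocorrelation so
that environment/pressure effects are not spatial artefacts. Centring
is what keeps the higher-order terms from being dominated by the
coordinate origin.

With D(X) = 1 − residual/null deviance for the model on predictor-set
union X, `partition_deviance()` fits the seven models E, P, S, EP,
ES, PS, EPS and returns

* pure fractions: a = D(EPS) − D(PS), b = D(EPS) − D(ES),
  c = D(EPS) − D(EP);
* three-way shared: g = D(E) + D(P) + D(S) − D(EP) − D(ES) − D(PS) +
  D(EPS);
* pairwise shared: d = D(E) + D(P) − D(EP) − g (and cyclic);
* unexplained: h = 1 − D(EPS).

The eight sum to one as an algebraic identity (asserted numerically
to 1e-10 on every fitted model). Shared fractions can be negative
when predictors suppress each other; they are flagged in printing and
never clamped. In the Gaussian/identity limit the partition
coincides with classical R² variance partitioning, and the suite
checks it against an independent linear-algebra oracle to 1e-8. All
seven sub-models share one family and one listwise-complete dataset
so the deviances are commensurable.

Whether partitioning should run over full variable sets or over
forward-selected subsets is genuinely open in the source description
("forward selection" and "the total variation was decomposed" appear
side by side). The package's default, `partition_selected()`,
forward-selects within each set against the response and partitions
over the selected subsets — the reading consistent with "minimal
adequate models" — and `select = FALSE` switches to full-set
partitioning.

## The synthetic survey generator

The generator (`simulate_sites()`, `simulate_densities()`) emulates
the survey design the analyses assume:

* 12 river types with the published morpho-climatic means and SDs
  (mean annual temperature °C, precipitation mm, altitude m, drainage
  area km²) and per-type site counts 28, 60, 68, 20, 28, 16, 33, 26,
  33, 22, 37, 9 — 380 sites in total. Variables are independent
  truncated normals per type (the typology publishes only marginals;
  a correlation structure could be added but the default is
  independence).
* A latent disturbance intensity u ∈ [0, 1] per site from a
  two-component Beta mixture — with probability 0.48 a
  low-disturbance Beta(1, 15), otherwise Beta(5, 2.5). Each pressure
  score is 1 + Binomial(4, u), so scores co-vary within a site as a
  disturbance syndrome and span the full gradient. These defaults
  were chosen once to reproduce the survey's roughly even
  reference/disturbed split (48% undisturbed by design; the rule
  classifies ~44–48% of simulated sites as reference) and are not
  tuning knobs.
* Chemistry covariates lognormal with log-mean increasing in u —
  baselines (e.g. BOD5 1.5, COD 8, TSS 5 mg/L) at pristine sites,
  climbing by 2–2.5 log units across the gradient.
* Coordinates uniform on the unit square: real geography is
  irrelevant to testing trend-surface machinery, where only relative
  positions matter.
* Densities: per site and species,
  λ = exp(intercept + Σβ·z) over z-scored configured predictors;
  realised density is a Poisson draw per 100 m², masked to zero with
  a covariate-independent probability (default 0.3 — the simplest
  mechanism producing the pervasive zeros of riverine density
  matrices; default intercept log 2 ind/100 m²). Densities are
  emitted directly rather than as counts over a sampled area, since
  sampled area per site is not part of the design being emulated.

What the generator does **not** emulate: inter-variable correlations
of the real landscape (altitude–temperature, drainage–discharge),
covariate-dependent zero inflation, species interactions, or
spatially autocorrelated residuals beyond what the injected
trend-surface coefficients produce. Passing recovery tests therefore
demonstrates that the machinery attributes deviance to the right set
under known structure — not that any particular field system behaves
this way.

## Numerical and procedural choices

* GLM convergence 1e-8 relative deviance, 100 iterations; separation
  and non-convergence are flagged, and downstream use of a flagged
  fit errors.
* Exact Mann–Whitney switches on at n1+n2 ≤ 12 (enumeration of
  C(12, 6) = 924 assignments at worst under ties).
* Partition sum-to-one asserted at 1e-10; Gaussian-limit oracle
  agreement at 1e-8; trend-surface centring at 1e-12.
* Degenerate inputs: SD-0 river types yield exact means; zero
  pressure everywhere is classified, not rejected; a survey without
  NNS short-circuits metrics to zero and skips partitioning with an
  explicit notice; a degenerate occurrence contrast (NNS everywhere
  or nowhere) skips the Z test with a notice rather than failing the
  run.
* Problem sizes in the default validation runs: recovery experiments
  use 20 replicate surveys of 500 sites per scenario; type-I
  calibration uses 2 000 null simulations per test; the Gaussian
  oracle toy uses 200 sites. These sizes give binomial/Monte-Carlo
  standard errors comfortably inside the asserted bands.

## Known limitations

* The raw field survey was never deposited, so data-dependent results
  (survey GLM coefficient tables, the published Venn fractions, the
  published Mann–Whitney statistics) cannot be reproduced — only the
  machinery and the printed-summary arithmetic are verifiable.
* The quality-class boundaries are a package default, not the
  (unpublished) original thresholds.
* Poisson-on-classes is inherited methodology; an ordinal model would
  be the textbook alternative and is out of scope.
* AIC forward selection admits occasional noise terms by
  construction (see above); interpret single-term membership in a
  selected model with the usual caution.
* No adjusted-R²-style correction of partition fractions, no
  eigenvector-based (PCNM/MEM) spatial descriptors — the cubic trend
  surface only.
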