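Package: fishinvade
Title: Drivers of Non-Native Fish Invasions in Mediterranean-Climate Rivers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical workflow for quantifying the invasibility of
    Mediterranean-climate river types by non-native fish. Scores human
    pressure on ten ordinal criteria and classifies sites against
    reference conditions; computes community invasibility metrics
    (frequency of occurrence, non-native richness fractions, pooled
    densities); provides a nonparametric toolbox (rank-transformation
    ANCOVA, Mann-Whitney with exact mode, two-proportion Z test,
    Spearman collinearity screening, first-axis PCA); fits
    binomial-logit and Poisson-log GLMs with VIF-constrained forward
    AIC selection; and partitions explained GLM deviance into eight
    pure and shared components across environmental, human-pressure
    and cubic trend-surface variable sets. Includes a synthetic survey
    generator with known effect structure so every stage is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
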