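Package: orbitype
Title: Orbital Morphotype Classification from Linear CT Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a three-type morphological classification of the human
    bony orbit from three linear dimensions (depth, height, width in mm).
    Provides a seeded truncated-normal mixture generator for synthetic orbit
    cohorts with optional age and sex covariate effects, the proportional
    shape indices (DI = D/W, WI = W/H, HI = H/W), published threshold
    decision rules (a full three-dimension algorithm and a depth-only
    fallback), and the derivation pipeline behind them: standardization,
    k-means (k = 3) with k-means++ seeding, cluster naming, linear
    discriminant analysis with stratified cross-validation, constrained
    decision-stump cut-off extraction, and depth-only cut-off optimization
    with percentile bootstrap confidence intervals. Group-comparison
    statistics (one-way ANOVA with eta-squared, Kruskal-Wallis, Mann-Whitney
    with rank-biserial correlation, Spearman's rho, Bonferroni-corrected
    Welch post hoc tests) and ggplot2 autoplot methods are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
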