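Package: metaeval
Title: Benchmarking Metabolomics Data-Processing Schemes Against
    Quantitative References
Version: 0.1.0
Authors@R:
    person("Metaeval", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to process semiquantitative (peak-area) metabolomics
    data and score how closely each processing recipe reproduces the
    multivariate structure of paired absolute-concentration data.
    Implements internal-standard based normalization (ccmn, nomis,
    single-IS ratio), six transformations (cube root, log2, log10,
    glog2, glog10, square root), six scalings (auto, level, pareto,
    power, range, vast), two-stage missing-value imputation (groupwise
    minimum substitution followed by iterative random-forest
    imputation), data-property diagnostics (Shapiro-Wilk normality,
    skewness, coefficient of variation, fold-difference trends,
    relative log abundance), PCA and NIPALS PLS-DA with variable
    importance in projection (VIP) scores, and a benchmark that
    enumerates the full 97-scheme processing grid and ranks schemes by
    VIP similarity to a concentration reference.  A paired
    concentration/peak-area simulator with milk-like and urine-like
    presets supports fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
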