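Package: depfdr
Title: False Discovery Control Under Strong Feature Dependence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for studying false-discovery
    control in high-dimensional two-group comparisons when features are
    strongly positively correlated, as in DNA methylation arrays. Generates
    plasmode-style synthetic data with beta or normal marginals and a
    block-correlated Gaussian-copula dependence structure, runs feature-wise
    tests (equal-variance t, empirical-Bayes moderated t, Wilcoxon rank-sum,
    one-sample Kolmogorov-Smirnov), applies ten family-wise error rate and
    false discovery rate procedures including a permutation-resampling FDR
    estimator, and quantifies per-dataset and ensemble error metrics (FPR,
    TPR, FDP, FDR, zero-discovery proportion) together with correlation-ECDF
    and negative-control diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    ggplot2,
    withr
Config/testthat/edition: 3
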