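Package: srdcor
Title: Significance Testing of Rank Cross-Correlations Between
    Autocorrelated Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Modified significance tests for Spearman's Rho and Kendall's Tau
    cross-correlations between time series that are individually autocorrelated
    (short-range dependent, beta-mixing). The classical iid-based test rejects
    far too often when both series are serially dependent; the modified test
    standardises the rank statistic by a kernel-weighted long-run variance
    estimated from lagged rank autocorrelations and restores the nominal
    type-I error rate. Includes the classical test for comparison, stochastic
    simulators (bivariate Gaussian VAR(1) and equal-weight vector moving
    averages with bivariate-t innovations), a Monte-Carlo harness for type-I
    error and power studies, and a moving-average smoothing pipeline for
    batch-testing many paired annual series (e.g. station networks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
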