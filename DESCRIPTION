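Package: survscreen
Title: Feature Screening for Right-Censored Survival Outcomes with
    Gene-Network Adjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marginal and network-adjusted feature screening for
    ultrahigh-dimensional covariates with right-censored survival outcomes.
    Implements seven univariate marginal screening utilities (marginal Cox
    partial likelihood, Pearson correlation, feature aberration at survival
    times, censored distance correlation and its composite-quantile variant,
    Harrell's concordance, and inverse probability-of-censoring weighted
    Kendall's tau) together with network-adjusted variants that smooth
    IPCW-tau utilities over a sparse conditional-dependence graph estimated
    by nonparanormal transformation and neighborhood selection. Ships a
    linear transformation-model survival simulator with AR(1), band, hub,
    cluster and scale-free covariate network structures, heavy-tailed
    contamination and calibrated uniform censoring; evaluation machinery
    (minimum model size, overlap coefficient, Jaccard similarity, c-index
    curves, test-set Cox deviance); and a train/test screening-and-fitting
    pipeline for expression plus clinical survival tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    glmnet,
    igraph
Suggests: testthat (>= 3.0.0), withr, jsonlite, yaml, optparse
Config/testthat/edition: 3
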