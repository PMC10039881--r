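Package: paleoccm
Title: Causal Inference and Regime-Shift Analysis for Paleoecological Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for empirical dynamic modeling of proxy time series:
    Takens delay embedding, simplex projection, convergent cross-mapping
    (CCM) with surrogate and ROC/AUC significance testing, time-delayed
    CCM for causal-direction rulings, smooth threshold-response (regime
    shift) detection with bimodality diagnostics, red-noise spectral
    analysis of unevenly sampled series, rolling correlations, and
    unit-variance PCA of XRF element tables. Includes seed-deterministic
    synthetic-data generators with known causal structure (coupled
    chaotic maps, an orbital-forcing to precipitation to hysteretic
    vegetation chain, factor-structured element counts) so every stage
    of the pipeline can be validated against recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    mgcv,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
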