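Package: mlmvcor
Title: Multilevel Multivariate Random-Effects Meta-Analysis of Correlation Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pools correlation matrices across primary studies when studies
    contribute multiple independent samples, using a three-level multivariate
    random-effects model: known Level-1 sampling (co)variances of Pearson
    correlations from large-sample (Olkin-Siotani) theory, per-cell within-study
    (Level-2) and between-study (Level-3) heterogeneity with structured
    (heteroscedastic) compound-symmetry covariance, REML or ML estimation,
    likelihood-ratio and information-criterion model selection, cluster-robust
    (CR2, Satterthwaite) inference, cell-by-moderator meta-regression with
    per-level variance explained, sensitivity sweeps over fixed random-effect
    correlations and the Fisher-z scale, and a seed-pinned generator of
    nested correlation-matrix datasets for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    generics,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
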