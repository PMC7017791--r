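Package: fluxgap
Title: Gap Filling and Annual-Sum Uncertainty for Eddy-Covariance CO2 Flux
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for post-processing half-hourly eddy-covariance CO2 flux
    records: quality-control screening (flag, diurnal-quantile, and median
    spike filters), seasonal nighttime friction-velocity (u*) threshold
    detection by a 45-level Wilcoxon scan, five gap-filling methods (marginal
    distribution sampling, Gaussian-process regression with an SE-ARD kernel,
    an empirical-Bayes hierarchical linear model, a single-hidden-layer neural
    network, and a radial-basis-function network), characterization of the
    random flux error (Laplace fit, Kendall tau by stratum, heteroscedastic
    sigma model), and stratified residual bootstrap of the annual carbon
    balance with bias and 95% confidence intervals, plus multi-method fusion.
    Includes a synthetic full-year flux generator for testing the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    nnet,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
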