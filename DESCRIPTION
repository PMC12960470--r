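Package: dlnmediate
Title: Distributed Lag Non-Linear Mediation Analysis of Temperature,
    Respiratory Infections and Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how much of cold-related mortality is
    mediated by acute respiratory infections (ARIs), using paired
    quasi-Poisson time-series regressions with distributed lag non-linear
    model (DLNM) cross-bases for temperature and ARI incidence.  Provides
    cross-basis construction from quadratic B-spline and natural cubic
    spline bases, cumulative exposure-response curves with minimum
    mortality temperature (MMT) estimation, backward-perspective
    attributable fractions and numbers with Monte-Carlo empirical
    confidence intervals, moving-window and monthly burden decompositions,
    weekly-to-daily disaggregation of ARI surveillance counts, and a
    synthetic data generator with known exposure-lag ground truth for
    validating the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    knitr,
    rmarkdown,
    jsonlite,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
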