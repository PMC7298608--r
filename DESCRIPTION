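Package: grainse
Title: Model-Based Geostatistical Mapping of Selenium in Staple Grain
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A model-based geostatistical pipeline for predicting the
    selenium concentration of staple cereal grain (teff and wheat) over a
    region from a joint soil-crop survey.  Implements sequential predictor
    selection under marginal false-discovery-rate control by
    alpha-investing, a trivariate spatial linear mixed model with a Matern
    linear model of coregionalization fitted by maximum likelihood or
    REML, factorial kriging analysis to split covariates into short- and
    long-range components, empirical best linear unbiased prediction
    (E-BLUP) by cokriging with prediction error variances, leave-one-out
    cross-validation with standardized squared prediction error
    diagnostics, and threshold-shortfall risk surfaces expressed on a
    calibrated verbal probability scale.  A synthetic survey generator
    with the statistical structure the analysis assumes makes every stage
    testable without external data.
License: GPL-3
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
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
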