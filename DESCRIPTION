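Package: phylomass
Title: Phylogenetically Informed Body Mass Estimation for Fossil Taxa
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits log-log allometries of body mass on femoral measurements
    (cortical cross-sectional area and length) under a Pagel's-lambda scaled
    phylogenetic covariance model, estimates lambda by maximum likelihood,
    selects among candidate models by AIC, predicts body mass with 95%
    prediction intervals for out-of-sample (fossil) specimens, aggregates
    specimen-level predictions into species-level weighted means, and compares
    estimate sets with paired tests on the log scale. Includes a seeded
    synthetic-data generator (pure-birth trees, correlated trait evolution,
    fossil placements) so the full pipeline is testable without restricted
    reference data, and a command-line entry point for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite,
    optparse
Config/testthat/edition: 3
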