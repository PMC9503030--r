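Package: spakit
Title: Peritoneal Transport Analysis for Standard Permeability Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes peritoneal membrane transport parameters from standard
    peritoneal permeability assessment (SPA) dwells: indicator-dilution
    residual volumes, net ultrafiltration, mass transfer area coefficients by
    the Garred log-ratio formula, total solute removal and clearance,
    dialysate-to-plasma and glucose D/D0 ratios, and body-surface-area
    normalization. Classifies peritonitis from effluent diagnostics and
    produces stratified descriptive summaries. Ships a seeded two-pool
    kinetic simulator of dwells (ultrafiltration, lymphatic absorption,
    sampling losses, measurement noise) with a ground-truth ledger, plus a
    longitudinal uremia trajectory generator, so every estimator is testable
    by closed-form oracles and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
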