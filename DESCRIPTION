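Package: spermCa
Title: Three-Compartment Calcium Homeostasis Modelling in Rat Round Spermatids
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Dynamic and steady-state modelling of cytosolic calcium in rat
    round spermatids. Implements a closed three-compartment (cytosol,
    endoplasmic reticulum, acidic vesicles) calcium flux model, the reduced
    two-variable post-thapsigargin dynamic system, a lactate -> ATP ->
    pump-activity steady-state quadratic, trace fitting by Nelder-Mead
    simplex minimisation over an adaptive Runge-Kutta 4/5 integration,
    exponential-decay steady-state extrapolation, cohort summary statistics,
    and seeded synthetic-data generators emulating fura-2 recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
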