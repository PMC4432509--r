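Package: phycoscreen
Title: Two-Step Nutrient-Screen Design and Growth-Curve Analytics for
    Microalgae Media Optimisation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design and analysis pipeline for high-throughput microalgae
    nutrient screening in 96-well plates. Generates the two-step screen
    designs (full-factorial nitrogen/phosphate Screen 1 and a ten-factor
    Box-Behnken Screen 2), maps conditions onto multi-plate layouts, fits
    variable-slope sigmoid models to OD750 growth curves with quality
    control and morphology triage, extracts maximum specific growth rates
    on the fitted 3-h grid, and runs second-order response-surface main-
    and interaction-effect analysis to rank media formulations. Includes
    a calibrated synthetic growth-curve simulator so the whole pipeline is
    testable without plate-reader hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
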