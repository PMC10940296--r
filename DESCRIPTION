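Package: cropsuit
Title: EcoCrop-Style Crop Suitability Modelling, Calibration and Validation
Version: 0.1.0
Authors@R: person("cropsuit", "maintainers", email = "maintainers@cropsuit.invalid",
    role = c("aut", "cre"))
Description: A mechanistic crop-suitability pipeline for gridded monthly
    climate and soil pH. Implements the EcoCrop trapezoidal climate-niche
    model with a 12-start-month growing-window search, iterative rainfall
    and temperature calibration against a yield-derived binary reference,
    sensitivity-specificity-equalized thresholding, multi-GCM scenario
    ensembling with archive-convention naming, a six-metric country- and
    occurrence-based validation framework, and a seeded synthetic-world
    generator so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
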