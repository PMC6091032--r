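Package: vco2ree
Title: Resting Energy Expenditure from Ventilator CO2 Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of resting energy expenditure (REE) in mechanically
    ventilated patients from carbon dioxide production (VCO2) alone, and a
    method-comparison toolkit for validating such estimates against indirect
    calorimetry. Implements the nitrogen-free Weir equation and its fixed
    respiratory-quotient VCO2-only estimators, six-hour ventilator block
    pairing, an agreement battery (bias, percentage error and difference,
    Pearson correlation, Lin's concordance correlation, ratio-band agreement),
    Bland-Altman analysis, and ridge-regression calibration with derivation of
    a rounded simplified formula. Includes a seeded synthetic ICU cohort
    generator emulating the statistical structure of published validation
    cohorts, so every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
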