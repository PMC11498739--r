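Package: cyhalotk
Title: Toxicokinetic Modelling and Urinary Dose Reconstruction for
    Lambda-Cyhalothrin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compartmental toxicokinetic model of the pyrethroid
    insecticide lambda-cyhalothrin (LCT) and its urinary biomarkers CFMP
    and 3-PBA. Provides exact matrix-exponential simulation of oral,
    dermal, inhalation and systemic exposures, multi-start ensemble
    estimation of kinetic rate constants from volunteer blood and urine
    time courses, Monte-Carlo reverse dosimetry of absorbed doses from
    worker urinary collections with occupational-exposure-limit
    exceedance probabilities, derivation of a biological reference value
    for urinary CFMP, exposure-scenario plausibility calculators, and a
    synthetic-data generator emulating volunteer dosing studies and
    worker biomonitoring series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
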