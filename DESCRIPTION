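Package: gpascent
Title: Steepest-Ascent Response-Surface Search for Genomic Prediction Accuracy
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates doubled-haploid populations and quantitative traits
    with a controllable additive/epistatic architecture and heritability,
    estimates cross-validated genomic prediction accuracy for
    ridge-regression BLUP and support-vector regression, and drives a
    steepest-ascent response-surface search (two-level full and fractional
    factorial designs, coded-variable first-order fits, basis step sizes,
    path evaluation) that locates the factor combination maximizing a
    chosen accuracy response while evaluating far fewer treatment
    combinations than the full factorial grid.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
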