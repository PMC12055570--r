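Package: ureatrace
Title: Quantification of In Vivo Ureagenesis from Oral [15N]Ammonium Tracer Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes the relative ureagenesis function (RUF) and tracer
    recovery from LC-HRMS isotopologue peak areas acquired after an oral dose
    of [15N]ammonium chloride. Covers the full analysis chain:
    internal-standard normalization, triplicate outlier rejection,
    missing-value imputation, percent [15N] isotopic enrichment curves,
    trapezoidal areas under the curve, urea-cycle label partition,
    tracer-recovery accounting, control reference ranges and
    pre/post-therapy comparisons, together with method-validation statistics
    (LLOQD, precision CV, mass accuracy, carry-over, plasma vs
    dried-blood-spot correlation, cohort tests) and a compartmental
    tracer-kinetics simulator that generates realistic control and
    urea-cycle-disorder cohorts for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
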