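Package: qams
Title: Single-Marker Quantification for Targeted LC-MS/MS Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of multicomponents by single
    marker (QAMS) in targeted LC-MS/MS (MRM) assays: weighted least-squares
    calibration, relative correction factors by the averaging (AVG) and
    linear-regression (LRG) estimators, single-marker and external-standard
    quantification, peak positioning by relative retention time plus
    transition identity, internal-reference screening, bioanalytical
    validation statistics (precision, stability, repeatability, spike
    recovery), robustness across chromatographic conditions, and
    external-standard versus QAMS method comparison. Includes a synthetic
    peak-table generator emulating an eight-constituent herbal preparation
    panel so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
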