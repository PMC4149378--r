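Package: stainkinetics
Title: Staining Kinetics of Iodine Contrast Agent in Soft Tissue from
    Micro-CT Image Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the penetration of iodine potassium iodide (I2KI)
    contrast agent into soft tissue from a time series of X-ray computed
    tomography slice images. Provides a synthetic phantom generator for
    annular tissue cross-sections, width-averaged intensity line-profile
    extraction with gradient-based detection of the outer tissue boundary,
    depth discretization of transmural profiles, exponential
    saturation-curve fitting of per-depth intensity time courses, and a
    log-linear model of required staining time versus tissue depth that
    supports staining-protocol planning, including dual-surface staining.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
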