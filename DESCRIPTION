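Package: calexit
Title: Calibrated Multi-Exit Convolutional Classifiers for Cytology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains convolutional image classifiers with early-exit auxiliary
    heads and an adaptively learned combination of all exits, targeted at
    small-to-medium cytopathology datasets such as urinary cytology screening.
    Provides focal-loss training, post-hoc temperature scaling, and a full
    calibration-evaluation suite (binned expected calibration error,
    reliability-diagram and confidence-histogram data, per-exit diagnostics),
    a patient-level preprocessing pipeline (centre four-crop, rotation
    augmentation, leakage-free splits), a synthetic cytology-image generator
    for fully reproducible experiments, and a seeded multi-run experiment grid
    with CSV reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    jpeg,
    withr,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
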