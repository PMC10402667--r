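Package: epidGDSA
Title: Gradient Dose Segmented Analysis of In-Vivo Transit EPID Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Longitudinal in-vivo quality assurance for VMAT radiotherapy
    from transit electronic portal imaging device (EPID) images. Builds
    per-fraction composite dose images, computes the gradient dose
    segmented analysis mean statistic (GDSA_mu) against a reference
    fraction, flags fractions whose mean high-dose low-gradient dose
    difference reaches 3%, and relates flagged fractions to effective
    body-separation change measured on the isocentre CBCT slice and to
    pitch/roll/yaw setup rotations extracted from rigid registration
    matrices. Includes a synthetic-patient generator with known ground
    truth (weight-loss transmission drift, shrinking elliptical body
    contours, couch-rotation drift) so the whole pipeline is testable
    without clinical data. Reads DICOM RT Image and Spatial Registration
    objects as well as portable plain-text arrays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    EBImage,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
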