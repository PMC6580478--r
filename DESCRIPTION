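Package: earsift
Title: Ear-Biometric Identification with Scale-Invariant Features Under
    Standardized and Freehand Image Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-set ear-biometric identification pipeline built on
    scale-invariant local features (SIFT): preprocessing (grayscale
    conversion, automatic aperture-ring cropping, fixed cropping,
    resizing), a native difference-of-Gaussians keypoint detector and
    128-dimensional gradient-histogram descriptor with a pluggable
    reference backend, Lowe ratio-test descriptor matching with
    one-to-one enforcement, bidirectional top-1/top-10 gallery
    identification and crop-sensitivity analysis, and study statistics
    (uncorrected chi-squared arm comparison, two-proportion sample-size
    planning, Pugh-chart scoring). Includes a seeded synthetic generator
    of paired-visit ear images contrasting a standardized, internally lit
    capture device with unstandardized freehand capture, so the effect of
    capture standardization on identification accuracy is reproducible
    without an external image set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
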