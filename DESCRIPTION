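Package: ctscatter
Title: Blocker-Array Measurement of Scatter and Scatter-to-Primary Ratio
    in Multi-Slice CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising scattered radiation in a 64-slice CT
    scanner with a one-dimensional lead beam-blocker array.  Detector
    channels in the shadow of the lead bars record scatter alone; open
    channels record total (primary plus scatter) radiation.  The package
    implements the full measurement chain: raw detector-frame I/O with
    calibration inversion, blocker-scatter compensation, shadow
    segmentation, monotone interpolation of the sampled scatter profile,
    primary radiation by subtraction, and per-channel and per-row
    (integrated) scatter-to-primary ratios.  A physics-based acquisition
    simulator - polychromatic tube spectra, Beer-Lambert ray tracing
    through cylindrical phantoms, and a single-scatter Compton Monte
    Carlo with a deterministic quadrature oracle - generates the raw
    frames the pipeline consumes, so the whole chain is testable without
    scanner hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
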