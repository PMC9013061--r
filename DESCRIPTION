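Package: msirecal
Title: Post-Acquisition Mass Recalibration for DESI Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-acquisition mass recalibration of desorption electrospray
    ionization (DESI) mass spectrometry imaging datasets using endogenous
    reference ions. Candidate reference masses from a lipid/metabolite
    database are matched across pixels within a ppm window, their
    pixel-order drift tracks are isolated with a 2D FFT kernel density
    estimate and a robust ridge spline, smooth drift trends are fitted with
    penalized-spline generalized additive models, and a per-pixel
    calibration model (linear for Orbitrap, square-root-domain polynomial
    with BIC degree selection for TOF) maps every observed mass to its
    recalibrated value. Includes imzML input/output, SVM-based tissue
    region-of-interest selection, a synthetic dataset generator with
    planted drift, and a bootstrap evaluation of accuracy improvement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    mgcv,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
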