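Package: climatch
Title: Cherenkov Luminescence Imaging Analysis of Radiotherapy Field Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring the match line between adjacent photon and
    electron radiotherapy fields from Cherenkov luminescence images (CLI).
    Implements the full measurement chain: background subtraction, temporal
    median over repeated CCD frames, 10x10 spatial median smoothing,
    composite/difference imaging of reference versus shifted acquisitions,
    ruler-based pixel-to-millimeter calibration, ROI profile extraction,
    FWHM-based matching-value estimation, and mean-grayscale/profile intensity
    metrics. A synthetic CLI generator emulates chicken-phantom photon and
    electron acquisitions (beam energy, dose rate, gantry obliquity, tissue
    color, CCD noise and sparkle impulses) so every stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
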