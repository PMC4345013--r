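Package: larvatrack
Title: Single-Animal Video Tracking Analysis of Drosophila Larval Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative phenotyping of Drosophila larval
    crawling from single-animal tracking video. Extracts a 13-point
    midline from high-contrast frames, reconstructs plate-frame
    trajectories from a motorized-stage log, detects peristaltic strides
    from the body-length oscillation, and computes a full panel of
    shape, peristalsis, stamina and track parameters per video, with
    batch processing, coefficient-of-variation reporting and
    same-day-control normalization for phenotypic profiling. Includes a
    synthetic peristaltic-crawler simulator with ground truth for
    validation and power analysis.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    png,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
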