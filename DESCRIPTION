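Package: skeletochron
Title: Skeletochronology of Bone Cross-Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying cyclical growth marks (lines of arrested
    growth and annuli) in transverse diaphyseal bone sections. Measures traced
    closed-contour tracings of the medullary cavity, growth marks, and
    periosteal surface (perimeter, cortical area, annulus centroid, principal
    axes, four-ray radial thickness), reconstructs per-element annual growth
    records including retrocalculation of marks destroyed by medullary
    expansion against a hatchling baseline, converts increments to daily
    apposition rates over a configurable growing season, and compares paired
    left/right elements with paired t-tests and pooled regression. Includes a
    synthetic growth-ring generator with full ground truth and the complete
    measurement tables for three juvenile American alligators as packaged
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
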