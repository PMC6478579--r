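Package: sfscore
Title: Structural Fragility Scoring of Distal Radius Bone Microarchitecture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes a structural fragility score (SFS) that quantifies joint
    cortical and trabecular deterioration of the distal radius from HR-pQCT
    cortical porosity and trabecular density, relative to a premenopausal
    reference. Fits the reference geometry (trait centroid, deterioration
    axis, maximum-deterioration point), decomposes subjects into off-axis and
    along-axis distances, and evaluates threshold-based fracture
    discrimination with exact binomial confidence intervals, Woolf odds-ratio
    intervals, and logistic adjustment. Includes a synthetic case-control
    cohort generator for validation without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
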