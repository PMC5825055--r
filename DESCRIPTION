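Package: agesal
Title: Age-Adapted Saliency Models and Gaze-Distribution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing how gaze distributions over natural scenes
    differ between observer age groups and for building age-adapted bottom-up
    saliency models. Implements fixation-map and Gaussian-smoothed human
    saliency-map construction, explorativeness entropy, thresholded-ROC
    agreement scores between age groups, and center-bias measures; three
    saliency models (a multi-scale center-surround model with age-specific
    scale-subset selection, a learned linear feature combination with
    age-weighted center bias, and a PCA patch-dissimilarity model with
    age-specific patch sizes); and a seeded synthetic observer-cohort
    simulator with controllable explorativeness, preferred regions and
    center bias, so every procedure is testable without eye-tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    jpeg,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
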