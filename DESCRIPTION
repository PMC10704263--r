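Package: muellerml
Title: Mueller Matrix Polarimetry Features and Patient-Level Recurrence Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transmission Mueller matrix polarimetry of collagenous
    tissue and for prognostic classification built on top of it. Simulates
    polarization-state intensity acquisitions, reconstructs per-pixel 4x4
    Mueller matrices by least squares, derives the standard polarimetric
    parameters (Lu-Chipman polar decomposition, Mueller matrix transformation,
    rotation-invariant quantities), aggregates pixels to region-of-interest
    records through an element-wise median Mueller matrix, and runs a
    patient-grouped cross-validated machine-learning workflow with
    majority-vote patient calls, feature-importance ranking and greedy
    outlier elimination. Includes a hierarchical synthetic cohort generator
    so the whole pipeline is exercisable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    vctrs,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    MASS,
    e1071,
    ranger,
    xgboost,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
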