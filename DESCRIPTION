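Package: vasoreact
Title: Vascular Reactivity from Block-Design BOLD fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts and models the stimulus-locked vascular reactivity
    response from block-design BOLD fMRI. A subject-level general linear
    model with a double-gamma haemodynamic response yields a Z-statistic
    activation map; a functional region of interest is built from the top
    fraction of activated voxels; the ROI-mean timeseries is cut into
    stimulus blocks, expressed as percent BOLD change, screened for
    artifact blocks, averaged, and summarised by a fitted trapezoid
    (time-to-peak, time-to-baseline, amplitude). Companion cohort
    statistics cover compound cognitive Z-scores, covariate-adjusted
    ANCOVA group contrasts, and thickness-cognition regressions with
    partial eta squared. A seeded synthetic-data generator produces 4D
    BOLD runs with planted trapezoidal responses and cohort tables with
    known effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
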