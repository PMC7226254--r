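Package: collatscreen
Title: Simulation and Analysis of a Collateral-Sensitivity Viability Screen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse an image-based collateral-sensitivity
    chemical screen on an isogenic pair of IL3-independent Ba/F3 reporter lines
    carrying an activating BTK mutation with or without an inhibitor-resistance
    mutation. Includes a synthetic-data generator (compound libraries with known
    effect classes, 384-well plate layouts, per-well viability counts, rendered
    fluorescence field images with ground truth, dose-response series, and
    clonal-competition trajectories), fluorescent cell counting by thresholding,
    8-connected segmentation and area/roundness/intensity filtering,
    DMSO-anchored viability normalization, a dual-dose differential
    drug-sensitivity score with quadrant-based hit classification, plate quality
    control via the Z-prime factor, and four-parameter log-logistic
    dose-response fitting for IC50 estimation and hit confirmation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    ggplot2,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
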