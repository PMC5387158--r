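Package: metavbq
Title: Simulated Metacognition Experiments and Voxelwise Quantitative-Map
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the link between perceptual metacognitive
    ability and quantitative brain-map measures with fully synthetic data.
    Simulates observers performing a dual-staircase global-motion
    discrimination task with retrospective confidence ratings, implements the
    type-II ROC (AROC) measure of metacognitive sensitivity together with the
    standard behavioural analysis chain (trial filtering, confidence quartile
    binning, d-prime and criterion, within-subject confidence-bias regression,
    staircase-stability repeated-measures ANOVA), generates per-subject 3D
    quantitative maps (MT, R1, R2*) with planted voxelwise effects, and runs
    mass-univariate voxelwise multiple regression with permutation-based
    familywise-error correction at peak (small-volume) and cluster level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
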