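Package: mitokin
Title: Phenotype Kinetics from Time-Lapse RNAi Screens of Nuclei
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of time-lapse, image-based siRNA knockdown
    screens that follow H2B-GFP-labelled nuclei: a ground-truthed synthetic
    screen generator (proliferating, transfection-synchronized populations,
    rendered nucleus images, plate layouts with spatial edge effects),
    region-adaptive nucleus segmentation with watershed cluster splitting,
    grey-value histogram normalization, per-nucleus texture and morphology
    features, frame-to-frame tracking with mitosis (split) detection,
    a class-weighted SVM-RBF phenotype classifier with nested
    cross-validation and posterior-based reliability filtering,
    trajectory-based label correction rules, B-score plate normalization,
    windowed phenotype-signal scoring with Wilcoxon rank tests, temporal
    candidate calling (cell death in or directly after mitosis), control
    quality checks, gene-list overlap enrichment, and cell-cycle period
    estimation from synchronized interphase dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    e1071,
    generics,
    ggplot2,
    graphics,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
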