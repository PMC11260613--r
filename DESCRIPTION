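Package: rtaccum
Title: Accumulated Dose Modelling for Combined External-Beam and Brachytherapy Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for accumulated-dose analysis of combined cervical-cancer
    radiotherapy. Converts external-beam (EBRT) and high-dose-rate
    brachytherapy (BT) dose grids to equivalent dose in 2 Gy fractions (EQD2)
    with the linear-quadratic model, warps and sums them on a common grid,
    builds the anatomical input channels used for voxel-wise dose prediction
    (unique-label structure maps and distance-to-target maps), trains and
    evaluates a residual encoder-decoder dose-prediction model with k-fold
    cross-validation, and scores dose distributions with DVH metrics (V50,
    V60, D2cc), dice similarity of isodose volumes, and Lyman-Kutcher-Burman
    normal tissue complication probability. Includes a seeded synthetic
    pelvic-phantom generator so the full pipeline can be exercised without
    patient data, and a plan-redesign aid based on the overlap between a
    predicted isodose volume and organs at risk.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
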