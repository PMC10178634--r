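Package: mammocad
Title: Contrast Enhancement, Feature Fusion and Flower-Pollination Feature
    Selection for Mammography Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale computational chain for mammography-based
    computer-aided diagnosis: hybrid contrast enhancement combining a
    histogram-equalisation style mapping with local-statistics contrast
    stretching, class-balancing geometric augmentation (horizontal flip,
    vertical flip, 90 degree rotation) with exact bookkeeping, a pluggable
    deep-feature extraction contract with a deterministic toy backbone,
    serial mid-value feature fusion, flower-pollination-controlled
    regula-falsi (FPcRF) wrapper feature selection with a 1-nearest-neighbour
    cross-validated fitness, and a cross-validated evaluation harness
    reporting precision, sensitivity, F1, FPR, Cohen's kappa, MCC, accuracy
    and margin-of-error confidence intervals. Synthetic fixture generators
    (mammogram-like images, planted-feature matrices) make every stage
    testable without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
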