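Package: retifocus
Title: Lesion-Focused Analysis of Retinal Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for lesion-focused diagnosis of common blinding
    ophthalmic diseases from colour fundus photographs. Provides a
    lossless bit-packed storage format (BITMAP) that packs up to 32
    binary lesion-mask channels into a single 8-bit RGBA PNG; a
    lesion-attention compositor that saturates the blue channel of a
    fundus image at segmented lesion pixels; compact U-Net
    (residual-encoder) segmentation and mobile-inverted-bottleneck
    classification model builders with a self-contained CPU training
    engine; screening statistics (ROC analysis, Youden-threshold
    selection, confusion matrices, micro/macro AUROC, odds ratios with
    Byar Poisson confidence intervals, bootstrap rate intervals,
    median-score risk stratification); and a synthetic fundus-image
    generator with paired ground-truth masks and patient-structured
    cohorts so the whole pipeline can be exercised end to end at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    EBImage,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
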