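Package: condylefd
Title: Automated Box-Counting Fractal Analysis of Condylar Trabecular Bone
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated box-counting fractal dimension (FD) analysis of
    trabecular bone regions of interest on panoramic dental radiographs.
    Implements the ten-step preprocessing chain (Gaussian background
    subtraction, binarization, morphology, skeletonization), box-counting FD
    estimation with log-log regression, synthetic fixtures with known fractal
    dimension, cohort simulation, normality-gated two-group statistics with
    effect sizes and Bonferroni correction, ICC(2,1) observer agreement, and a
    six-classifier cross-validated benchmark for discriminating
    temporomandibular-disorder patients from controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    class,
    e1071,
    jsonlite,
    png,
    randomForest,
    stats,
    tiff,
    tools,
    utils,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
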