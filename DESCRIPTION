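Package: absig
Title: Plasma Analyte Biomarker Signature Discovery by Combinatorial Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering multivariate plasma-proteome biomarker
    signatures from multiplex immunoassay panels. Implements detection-limit
    flooring and detectability filtering, single-cut entropy discretization with
    a minimum-description-length acceptance criterion, exact and heuristic
    solvers for the (alpha,beta)-k feature set selection problem with
    maximum-coverage tie-breaking, analyte-pair meta-features built from
    Z-scores, a multi-classifier evaluation harness reporting Matthews
    correlation coefficients under cross-validation and matched train/test
    protocols, longitudinal change signatures with a control-stability filter,
    and memetic seriation of heat-map matrices. A synthetic panel generator
    with planted ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    class,
    e1071,
    rpart,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    withr
Config/testthat/edition: 3
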