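Package: vertebraDS
Title: Vertebral Endplate Surface Roughness Scoring and Age Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies cortical surface roughness of isolated antero-superior
    vertebral endplate images as the mean nearest-point distance of the
    extracted boundary to a penalized least-squares fitted ellipse (the DS
    score), and models chronological age from per-vertebra DS panels.
    Provides Otsu thresholding and external contour tracing with baseline
    removal, PCA-initialized bounded least-squares ellipse fitting with
    tangential, curvature and eccentricity penalties, sex-stratified cohort
    statistics (descriptives, rank correlations, ANCOVA interaction screen,
    multiple linear regression with collinearity diagnostics, LASSO),
    machine-learning age regressors (SVR, random forest, k-NN and a
    discretized Gaussian naive-Bayes pseudo-regressor) with leakage-free
    fold-wise standardization and bootstrap confidence intervals, post hoc
    power analysis for the overall regression F-test, and synthetic phantom
    and cohort generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    glmnet,
    e1071,
    randomForest,
    caret,
    png,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    car
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
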