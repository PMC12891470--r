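Package: gaitstab
Title: Trunk-Accelerometry Gait Stability Metrics and a Two-Step
    Machine-Learning Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes linear and nonlinear trunk-acceleration gait stability
    indicators (speed-normalized RMS, harmonic ratio, sample entropy,
    recurrence quantification, short-term maximum Lyapunov exponent) from
    segmented lumbar accelerometer signals, together with EMG co-contraction
    and joint-angle predictors, and runs a two-step analysis: (1) discriminate
    stroke-like from control-like gait with augmentation-aware classifiers and
    sparse PLS-DA with VIP scores, and (2) predict uneven-surface stability
    metrics and gait speed from even-surface parameters with interpretable
    regression (odds ratios, permutation Shapley attributions, partial
    dependence). A synthetic-cohort generator with known ground truth makes
    every stage testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    ranger,
    e1071,
    rpart,
    xgboost,
    caret,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mixOmics,
    car,
    randomForest
Config/testthat/edition: 3
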