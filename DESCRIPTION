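Package: annpso
Title: Obesity Risk Classification with a Particle-Swarm-Trained Neural Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete tabular pipeline for seven-level obesity risk
    classification from dietary-habit and physical-condition survey
    attributes. The classifier is a feedforward neural network whose
    flattened weight vector is trained by particle swarm optimization
    with a linearly decaying inertia weight, using mean squared error on
    softmax outputs as the swarm fitness. The package ships the survey
    data schema with BMI computation and WHO-based class tables, feature
    engineering (meal habits, activity balance, technology-usage score,
    transport-mode activity recoding, height removal), SMOTE class
    balancing, stratified splitting and k-fold utilities, a
    class-conditional synthetic data generator emulating the survey
    schema, evaluation tools (confusion matrices, per-class
    precision/recall/F1, one-vs-rest ROC and precision-recall curves
    with AUC, permutation feature importance), ggplot2 autoplot methods
    and broom-style tidiers, and a reproducible end-to-end pipeline
    runner with a YAML run configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
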