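Package: dtoprs
Title: Dipper-Throated Optimization with Polar Rose Search for Feature
    Selection and RBF Network Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A population-based optimization framework built around the
    Dipper-Throated Optimization (DTO) algorithm and its hybridization with
    a Polar Rose Search (PRS) diversification operator that perturbs elite
    solutions along rhodonea (rose) curves. Provides continuous and binary
    (sigmoid-transfer) variants for wrapper feature selection, a radial
    basis function network (RBFN) classifier with closed-form ridge output
    weights and metaheuristic hyperparameter tuning, six canonical baseline
    swarm optimizers (GWO, PSO, BA, WOA, SBO, FA) behind a common contract,
    exact Wilcoxon signed-rank and one-way ANOVA validation utilities,
    confusion-matrix classification metrics, and a synthetic water-quality
    style tabular data generator with a leakage-free preprocessing chain
    (skew-guided imputation, min-max normalization, stratified splitting
    and cross-validation folds).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
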