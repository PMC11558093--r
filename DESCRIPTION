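Package: omegrow
Title: Multi-Omics Expression Compendia, Metabolism-and-Expression Models,
    and Machine-Learning Growth Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assembling a normalized multi-source gene-expression
    compendium (identifier harmonization, min-max scaling, magnitude-outlier
    removal, random-forest imputation), fitting transcription-factor to
    target-gene regression networks with per-edge confidence, building and
    solving desk-scale metabolism-and-expression (ME) models whose
    stoichiometric coefficients depend on the growth rate, a machine-learning
    harness for growth-rate prediction (HDMPPK feature engineering, sparse
    group lasso, four model families, five hyperparameter optimizers,
    repeated evaluation), two-view ensemble combination, and an integration
    loop that feeds ME-model simulations into the learners and updates the
    ME model from learned growth and expression targets.  Synthetic-data
    generators with recorded ground truth make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    randomForest,
    FNN,
    e1071,
    xgboost,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
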