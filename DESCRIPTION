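Package: qsarscreen
Title: Hybrid Linear/Neural QSAR Modelling and Ligand-Based Virtual Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds quantitative structure-activity relationship (QSAR)
    regression models for logIC50 prediction from molecular descriptor
    tables and ranks compound libraries with them. Provides descriptor
    preprocessing (variance and activity-correlation filters, min-max and
    z-score scaling), best multilinear regression (BMLR) stepwise subset
    search with full ordinary-least-squares diagnostics, leave-one-out
    cross-validation via the hat matrix, leverage-based training-set
    reduction, ABC three-fold external validation, a feed-forward neural
    network regressor trained from scratch by the generalized delta rule
    (online back-propagation with momentum and validation-based early
    stopping), descriptor-range applicability-domain screening, and
    consensus ANN+MLR ranking of screening libraries. A synthetic-data
    generator with known ground truth makes every stage testable without
    external descriptor software or bioactivity databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
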