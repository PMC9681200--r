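Package: depnet
Title: Personalized Protein-Interaction Networks for Predicting Cancer
    Cell-Line Gene Dependencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Personalizes a generic protein-protein interaction network per
    cancer cell line using mutation and expression profiles (loss-of-function
    node deletion and expression-driven directed edge weighting), extracts
    twelve graph-topology features per gene, and trains and evaluates
    random-forest classifiers that predict cell-line-specific gene
    dependencies from DepMap-style dependency-probability matrices. Includes
    degree-preserving rewired and edge-ablated null networks, balanced
    train/validation/test splitting, rarity-stratified and cross-cell-line
    evaluation, leave-one-feature-out importance, siRNA screen concordance
    helpers, and a fully seeded synthetic-cohort generator so the whole
    pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
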