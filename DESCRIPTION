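Package: scHypoxia
Title: Single-Cell Hypoxia State Scoring, Consensus Labeling and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Characterises cellular hypoxia in single-cell RNA-seq data.
    Computes per-cell single-sample gene-set enrichment (ssGSEA) activity
    scores for a panel of hypoxia gene sets, labels high-confidence hypoxic
    and normoxic cells by a two-component Gaussian-mixture consensus across
    all gene sets, derives a hypoxia gene signature by Wilcoxon rank-sum
    testing, builds cell-embedding or raw-expression feature matrices, and
    benchmarks a panel of machine-learning classifiers across training-set
    fractions to pick the model that classifies the remaining low-confidence
    cells. A negative-binomial simulator with planted hypoxic, intermediate
    and normoxic populations supports validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    BiocGenerics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    ranger,
    rpart,
    nnet,
    xgboost,
    lightgbm,
    catboost,
    mclust,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
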