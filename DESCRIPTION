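Package: snslink
Title: Shared Neighborhood Scoring for Tripartite Pharmacological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Link prediction on heterogeneous drug-protein-disease networks
    with the shared neighborhood score: common-neighbor counting extended by
    probability-weighted virtual links, per-category logistic calibration of
    the connection probability P(n), score normalization, leave-one-out
    evaluation (Kolmogorov-Smirnov distribution comparison and ROC/AUC of the
    simple versus extended score), a planted-community synthetic network
    generator with seeded link holdout, and a drug-repositioning candidate
    filter. Edge lists are plain TSV; results are tibbles designed for
    pipe-based workflows.
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
    jsonlite,
    Matrix,
    methods,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
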