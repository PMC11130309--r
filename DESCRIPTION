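Package: tamscreen
Title: Differential Ligand-Receptor Interaction Screening Across Replicated
    Tumor Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how tumor-associated macrophage (TAM) states
    shape therapy response in replicated single-cell experiments. Provides a
    negative-binomial synthetic single-cell and patient-cohort generator with
    planted ligand-receptor programs, cell-level quality control and hashtag
    demultiplexing, marker-rule lineage and myeloid-subtype annotation, a
    permutation-based ligand-receptor interaction caller, a replicate-pairwise
    differential interaction-count statistic with a discordance screen,
    rank-based signature scoring, and patient-level myeloid-ratio outcome
    statistics (ROC, Kaplan-Meier/log-rank, univariate Cox).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    igraph,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
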