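Package: ecmstates
Title: Consensus NMF Discovery and Classification of Extracellular Matrix
    Expression States in Bulk Tumor Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovers extracellular-matrix (ECM) expression states in
    multi-cohort bulk RNA-seq data by consensus non-negative matrix
    factorization on a matrisome-restricted, batch-corrected logCPM matrix;
    selects the factorization rank by the cophenetic correlation
    coefficient; defines core samples by silhouette on the consensus
    matrix; validates gene-set stability by bootstrap resampling against a
    bin-matched control-gene null using the Adjusted Rand Index; derives
    cross-cohort subtype signatures by per-dataset Wilcoxon testing;
    scores and classifies external bulk and pseudobulk samples with
    expression-bin-matched control genes; derives cell-type marker
    metagenes from labeled single-cell matrices; and tests the association
    of states and metagene strata with overall survival by Kaplan-Meier
    estimation and the log-rank test. Includes a synthetic-data module
    that generates multi-cohort negative-binomial counts, survival times
    and toy single-cell matrices with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Matrix,
    cluster,
    edgeR,
    limma,
    survival,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
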