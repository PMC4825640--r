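Package: gsld
Title: Genomic Prediction with Linkage-Disequilibrium-Aware Marker
    Transformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Benchmarking toolkit for genomic selection in half-sib family
    breeding programs. Calls expected allelic dosages from sequencing read
    counts by a per-marker expectation-maximization algorithm, fits half-sib
    family BLUPs from multi-year randomized-complete-block trials by REML
    (optionally with a first-order-autoregressive spatial plot effect),
    builds block-diagonal marker correlation matrices and LDAK-style tagging
    weights, produces four linkage-disequilibrium-aware marker-data
    transformations (Base, PCA, Cor, LD), and evaluates nine prediction
    models (GBLUP, RKHS, their weighted and selected variants, BayesA,
    BayesB, random forest) under within- and across-population and
    -environment learning schemes, using replicated cross-validation with
    correlation-adjusted paired Dunnett tests. Supporting genetic analyses
    include bivariate genomic correlations, EMMAX-style association scans
    with forward-BIC multi-marker models, and multi-kernel partition of
    genomic heritability by degree of tagging. A synthetic-data generator
    emulating two populations with contrasting LD decay makes the whole
    pipeline testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    randomForest,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
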