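Package: gsanorm
Title: Multivariate Normality Testing and Gene-Set Analysis Benchmarking for Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the multivariate-normality (MVN) assumption in
    gene expression data and to benchmark functional-class-scoring gene-set
    analysis (GSA) tests under departures from it. Implements six MVN
    goodness-of-fit tests (Mardia, Henze-Zirkler, Royston, Fattorini FA, TN,
    energy), eight self-contained GSA tests (global test, Hotelling T2,
    rotation testing, pathway activity score, self-contained GSEA,
    N-statistic, and minimum-spanning-tree Kolmogorov-Smirnov tests of mean
    and variance), a gene-subset rejection-rate protocol, a mixture-model
    simulation framework with multivariate normal and heavy-tailed
    t-components representing disease subtypes, and a k-nearest-neighbour
    Kullback-Leibler divergence estimator. Readers and writers for dense and
    sparse expression matrices, GMT gene-set collections and sample labels
    are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    Matrix,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
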