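Package: sphingonet
Title: Serum Sphingolipidomic Characterization of Metabolic Syndrome via
    Correlation-Distance Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing metabolic syndrome (MetS) from serum
    sphingolipidomic profiles. Implements ATPIII MetS classification with
    medication overrides, sphingolipid preprocessing (missingness filtering,
    log/z-score harmonization, ceramide/glycosphingolipid ratio biomarkers),
    Wilcoxon/fold-change volcano screening, covariate-adjusted linear and
    logistic association matrices, and absolute-Spearman correlation-distance
    network analysis with Benjamini-Hochberg edge thresholding, fast-greedy
    modularity clustering, interclass-distance permutation tests, and
    Steiger-type whole-network comparison across MetS/CRP strata. A seeded
    synthetic cohort generator with class-blocked lognormal abundances makes
    the full pipeline runnable and testable without cohort data in hand.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Lipidomics, Metabolomics, Network, GraphAndNetwork, Classification
RoxygenNote: 7.3.3
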