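Package: hyperloopR
Title: Detection of Statistically Significant Multi-Way Chromatin Contacts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects hyperloops, i.e. statistically significant multi-way
    chromatin contacts whose loci are connected by pairwise chromatin loops,
    from SPRITE- or Pore-C-style multi-way interaction clusters. Clusters are
    binned per chromosome, decomposed into a Hi-C-like pairwise contact matrix
    that is balanced by iterative correction to estimate per-bin technical
    biases, and screened with a distance-decay binomial loop caller (or loops
    imported from BEDPE). Frequent multi-way bin sets are enumerated with an
    FP-growth miner, filtered for loop connectivity, and assigned significance
    under a bias-aware binomial background model built from size-specific
    genomic-distance distributions of pairwise contacts, with size-stratified
    Benjamini-Hochberg correction. Includes a synthetic-data generator with
    known ground truth, shuffle-based empirical false discovery rate
    estimation, and goodness-of-fit diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    parallel,
    Matrix,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'background-model.R'
    'cluster-io.R'
    'connectivity.R'
    'contact-matrix.R'
    'evaluation.R'
    'hyperloopR-package.R'
    'loop-calling.R'
    'mining.R'
    'pipeline.R'
    'synthetic.R'
    'utils.R'
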