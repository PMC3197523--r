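Package: sutureGIC
Title: Probe-Coherence Screening and Differential Expression for
    Single-Suture Craniosynostosis Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end probe-level microarray analysis for case-control
    transcriptomic studies of single-suture craniosynostosis (sagittal,
    coronal, metopic). Implements a per-gene probe-coherence statistic, the
    Gene Information Content (GIC) score: the fraction of probe-level
    variance explained by the first singular value of each gene's centered
    probe-by-sample block, with a permutation-derived significance cutoff
    obtained by shuffling the probe-to-gene map. Around it: quantile
    normalization and median-polish probe-set summarization, covariate-
    adjusted moderated differential expression with batch blocking (via
    limma), percent-change effect-size filtering, three-way Venn set
    partitioning, two-dimensional hierarchical clustering, gene-set
    over-representation analysis on GMT collections, and a synthetic
    probe-level data generator emulating the study design for testing and
    power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    limma,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    statmod,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Microarray, GeneExpression, DifferentialExpression,
    Preprocessing, Clustering, Pathways
RoxygenNote: 7.3.3
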