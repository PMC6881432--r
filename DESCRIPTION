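Package: phasecore
Title: Core Transcriptional Signatures of Locust Phase Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies core transcriptional signatures of density-dependent
    phase polyphenism from heterogeneous bulk RNA-seq designs. Implements
    confounding-adjusted principal component analysis (AC-PCA) with penalty
    tuning and projection-sign phase prediction, directional Borda (median)
    aggregation of per-dataset gene rankings into a PhaseCore gene set with
    leave-one-out and cross-dataset validation, gene-attribute measurements
    (specificity index tau, CpG observed/expected, gene-body methylation,
    topological-overlap connectivity, no-replicate differential expression),
    an ensemble transcriptional regulatory network built from mutual
    information (CLR, ARACNE), tree-based importance, topological overlap,
    shrinkage partial correlation and module-based scorers, hypergeometric
    TF-target enrichment with Benjamini-Hochberg adjustment, and a logistic
    behavioral phase classifier. A synthetic-study generator emulating the
    development, tissue and phase-transition time-course designs makes the
    whole pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    edgeR,
    limma,
    Biostrings,
    ranger,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
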