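Package: ironasym
Title: Gene-Set Induction Asymmetry Analysis for Iron-Deficiency RNA-Seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tests whether a focal set of iron-deficiency-inducible genes
    (FIT-dependent Strategy I iron acquisition genes) is disproportionately
    more induced in a chromatin mutant (clf, lacking PRC2-mediated H3K27me3)
    than a comparator set (PYE-dependent genes). Provides a seeded
    negative-binomial count simulator for the 2 genotype x 2 iron-condition
    x n replicate design, median-of-ratios normalization, FPKM, per-genotype
    minusFe/plusFe fold changes, a simplified negative-binomial Wald test
    with Benjamini-Hochberg FDR, the above-diagonal proportion statistic
    with a label-randomization null and a tie-corrected Mann-Whitney U test,
    qRT-PCR delta-Ct relative expression and ChIP-qPCR percent-of-input
    calculators, and z-score/hierarchical-clustering/over-representation
    utilities for iron-regulated gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
biocViews: Transcriptomics, RNASeq, DifferentialExpression, GeneSetEnrichment,
    Epigenetics
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
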