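Package: syncomtx
Title: Reference-Guided Metatranscriptomics for Synthetic Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for strain-resolved metatranscriptome analysis of synthetic
    microbial communities (SynComs) colonizing a host. Implements duplicate-aware
    read-to-gene assignment across many strain genomes via k-mer identity
    classes, RNA-based community profiling, per-strain and community-scale
    (orthogroup) negative-binomial differential expression with log-fold-change
    shrinkage, cross-strain cumulative-log2FC ranking of conserved responses,
    Fisher-exact functional enrichment, function-abundance regression, and
    Bray-Curtis/PCoA/PERMANOVA transcriptome ordination. Ships a synthetic
    SynCom generator with full ground truth so every stage is testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    data.table,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    vegan,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    DESeq2,
    SummarizedExperiment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
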