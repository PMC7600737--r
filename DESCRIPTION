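Package: poolsweep
Title: Selection-Signature Scans from Pooled Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("poolsweep", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects selective sweeps in multi-population pooled sequencing
    (Pool-seq) data. Reads pooled VCFs with per-population allele depths,
    applies quality/coverage filters, computes pooled heterozygosity (Hp) and
    its Z-transform (ZHp) in sliding windows, pairwise Fst via an
    among/within mean-squares estimator and the population-specific di
    statistic, and calls selected loci as windows jointly extreme in both
    statistics, annotated with overlapping genes. Includes a synthetic
    Pool-seq generator (Balding-Nichols differentiation with planted sweeps)
    and a conserved-site screen of breed-specific variants against
    multi-species alignments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
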