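Package: gcregulome
Title: Glucocorticoid Regulatory-Response Analysis for Leukemia Functional Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for dissecting glucocorticoid (GC)
    gene-regulatory responses in acute lymphoblastic leukemia functional
    genomics data. Implements negative-binomial differential testing of
    region and gene counts, super-enhancer calling by rank-ordering of
    stitched H3K27ac regions with a tangent cutoff, high-confidence
    glucocorticoid-receptor site (HGR) calling with GRE motif annotation,
    STARR-seq enhancer-activity calling by binomial and count-model
    routes, differential transcription-factor footprinting, CRISPRi
    tiling-screen aggregation by alpha-robust-rank aggregation,
    HiChIP loop annotation and linkage statistics, and genetic and
    epigenetic fine-mapping of GC-resistance loci with allele-specific
    motif scoring. A synthetic-data module generates every input with
    planted ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
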