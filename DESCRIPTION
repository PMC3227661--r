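Package: mmsdk
Title: Multi-Omics Tag Sequencing: Methylation-Sensitive Digital Karyotyping
    and Digital Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for restriction-digest tag
    sequencing of tumor/normal pairs: in-silico MluI/NlaIII digestion of a
    genome into MMSDK methylation tag libraries and NlaIII (CATG) digital
    gene expression tag references, CpG-island detection, read cleaning and
    adapter clipping, exact/1-mismatch unique tag mapping, per-locus
    counting and replicate pooling, the Audic-Claverie Poisson test for
    differential tag abundance with Benjamini-Hochberg FDR control, miRNA
    target-consensus filtering, hypergeometric gene-set enrichment, and
    gene-level integration of promoter methylation with expression. A
    seeded synthetic-data generator emulates the matched tumor/normal
    study design so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
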