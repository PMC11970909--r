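Package: cooccmap
Title: Promoter Chromatin States, Broad H3K4me3 Domains, and
    Transcription-Factor Co-Occupancy Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of promoter chromatin state and
    transcription-factor co-occupancy from peak and fragment interval
    data. Provides BED/narrowPeak readers and a genomic interval engine;
    strand-aware promoter windows with RPKM fragment quantification;
    k-means clustering of H3K4me3/H3K27me3 promoter signal into four
    chromatin states; TSS-anchored H3K4me3 domain breadth classification
    (narrow/medium/broad) and top-5% broad-domain (BD) calling;
    genotype-differential domain signal to define BD genes with reduced
    H3K4me3; gene-level binding-set Venn and co-occupancy fractions;
    per-element WGBS CpG methylation summaries; single-cell TCR
    clonotype expansion and cross-cluster sharing statistics; and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
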