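Package: enhancerTargets
Title: Enhancer-Centric Inference of Direct Target Genes from
    Histone-Mark ChIP-Seq and Knockdown RNA-Seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies active enhancers from overlapping distal H3K4me1
    and H3K27ac ChIP-seq peaks, classifies enhancers whose signal drops
    after knockdown of an enhancer-regulating chromatin factor (e.g. the
    H3K4 methyltransferase MLL3/KMT2C), links enhancers to genes by TSS
    distance, and intersects repressed-enhancer-linked genes with
    direction-consistent differentially expressed genes from dual-siRNA
    RNA-seq to nominate direct target genes. Includes RPKM region
    quantification, signal-matrix/aggregate-profile construction,
    ChIP-qPCR percent-input and 3C crosslinking-frequency arithmetic, and
    a synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Epigenetics, FunctionalGenomics, GeneRegulation, ChIPSeq,
    RNASeq, Coverage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
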