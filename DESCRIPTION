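Package: methimprint
Title: Windowed Methylome Analysis of Oocytes, Embryos and Molar Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tile-based quantification of sparse single-cell and bulk bisulphite
    methylation calls and of methylation-array beta values, segmentation of
    reference germline methylomes into methylated and unmethylated domains,
    methylation scoring of imprinted germline DMRs and CpG islands,
    hypomethylated-region calling in molar tissue against control placentas,
    embryo-to-oocyte methylation maintenance ratios, and ZFP57 binding-motif
    methylation in single oocytes. Includes a synthetic-data generator that
    builds a toy genome with planted methylation domains, imprinted DMRs and
    ZFP57 motifs so that every stage of the pipeline can be verified against
    planted ground truth.
License: MIT
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
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
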