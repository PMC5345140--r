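Package: cryptmeth
Title: Promoter Methylation, CpG Classes, and Transcription-Factor Target
    Calling for Intestinal Crypt Epigenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for two-group promoter methylation studies on
    MeDIP (methylated-DNA immunoprecipitation) tiling arrays and their follow-up
    assays. Assembles enrichment peaks from probe-level log2(MeDIP/Input)
    ratios, calls differential methylation enrichment peaks (DMEPs) under
    median-enrichment and coefficient-of-variability filters, classifies
    promoters into high/intermediate/low CpG-density classes by windowed GC
    fraction and CpG observed/expected ratio, scores bisulfite clone matrices,
    annotates ChIP-seq peaks to promoters, exons, introns, enhancers and
    extended enhancers with strand-aware TSS offsets, and integrates
    knockdown/overexpression qPCR and dual-luciferase readouts into
    activator/repressor target calls. A synthetic-data generator with known
    ground truth emulates the array and sequencing designs for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
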