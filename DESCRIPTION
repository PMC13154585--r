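Package: translatomics
Title: Translatome Profiling Analysis for Paired RNA-Seq and Ribo-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis toolkit for paired bulk RNA-seq and ribosome
    profiling (Ribo-seq) studies of tumour versus normal tissue. Provides
    Ribo-seq quality control (P-site offset calibration, 3-nt periodicity,
    read-region partitioning), consolidation of per-sample de novo ORF calls
    into a classified catalog with tumour-specificity classes, negative
    binomial GLM testing of differential expression and differential
    translation efficiency with an interaction model and a four-class
    regulatory categorization (forwarded, exclusive, intensified, buffered),
    comparison of 5'UTR regulatory features (uORF, TOP, AU content, IRES,
    m6A) between gene sets, a simplified weighted co-expression module and
    hub-gene analysis of translation-efficiency profiles, and exact substring
    matching of immunopeptides to ORF translations. A synthetic-data
    generator with planted ground truth exercises every stage without access
    to the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
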