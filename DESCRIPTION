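Package: repeatloop
Title: Repetitive-Element Enrichment Analysis for R-Loop Peak Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the association between repetitive elements
    and R-loop formation from interval data. Computes base-level overlap of
    DRIP-seq R-loop peaks with RepeatMasker repeat annotations at the repeat
    class and family level, builds three control backgrounds (whole genome,
    GRO-seq transcribed regions, and a 1000-draw resampling null matched for
    peak number, length, and genomic-location category), and reports two
    enrichment statistics: the log10 ratio of base percentages and the Z-score
    of the observed percentage against the resampling null. Includes a genome
    partitioner (promoter2k/terminator2k/exon/intron/intergenic with priority
    assignment), readers for BED, chrom.sizes, UCSC rmsk tables, RepeatMasker
    .out and GTF/GFF3, and a synthetic-data generator with planted, recorded
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
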