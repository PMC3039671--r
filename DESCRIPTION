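Package: broadcall
Title: Broad-Region ChIP-Seq Peak Calling with Input-Driven Normalization
    and Shuffle-Calibrated FDR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls broad enrichment domains for spreading histone marks
    (H3K9me3, H3K36me3 and similar) from mapped ChIP-seq tags.  The input
    channel is used to detect genomic duplications, deletions and
    over-sequenced artifact regions so that the ChIP signal can be
    normalized to a single-copy, bias-free genome; tracks are smoothed
    with a sliding average so jagged "mountain range" profiles merge into
    contiguous binding regions; and the height cutoff is calibrated at a
    user-defined false discovery rate by shuffling input tags within
    megabase sampling bins.  Also provides the downstream dual-mark
    analytics (interval Venn overlap, per-kilobase tag and motif
    densities, promoter/intragenic/intergenic classification, nearest
    genes, repeat-fraction histograms, zinc-finger-domain association,
    allele-fixation classification) and a seeded synthetic ChIP-seq
    generator with planted domains, copy-number segments and
    over-sequenced hotspots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    methods,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
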