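Package: irscore
Title: Intron Retention Scoring from Splice-Junction Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide intron retention analysis for short-intron-rich
    transcriptomes. Counts reads traversing exon-exon, exon-intron and
    intron-exon junctions of each annotated intron, computes per-replicate
    intron retention scores (IRS) and condition-level two-sample Z tests,
    classifies introns into strongly/mildly affected and unaffected sets,
    analyses splice-site sequence features (position matrices, differential
    logo profiles, exonic signature groups, U5 snRNA loop1 pairing) and
    intron-length-stratified splicing defects. Includes a synthetic-data
    generator producing a toy short-intron genome, annotation and spliced
    alignments with known ground truth for validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
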