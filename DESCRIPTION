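Package: novelscope
Title: Novelty Scoring, Conservation and Splicing Profiles for Assembled Transcriptomes
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Characterizes assembled transcript models against a reference
    annotation across developmental stages. Computes a per-transcript novelty
    score (the percentage of exonic length not covered by annotated exons) and
    classifies transcripts as known, partially novel (PNT) or completely novel
    (CNT); aggregates per-base phastCons conservation exon-by-exon into a
    transcript conservation score; summarizes stage-wise TPM expression with
    replicate averaging, max-normalization and stage-specificity calls; applies
    compound high-confidence filters; detects open reading frames in six frames
    with canonical and near-cognate start codons; estimates percent-spliced-in
    (PSI) from junction counts with a Fisher exact screening step; and exports
    genome-browser BED tracks. A synthetic-data module generates annotation,
    transcripts, conservation tracks, expression matrices, junction counts and
    sequences with known ground truth so the whole pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    data.table,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
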