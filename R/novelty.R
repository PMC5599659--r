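#' Exonic overlap between a transcript and the annotated exonic union
#'
#' Counts the number of exonic bases of one transcript covered by the
#' annotation's merged exonic union. Counting is per base with no double
#' counting. A chromosome absent from the annotation simply contributes zero
#' overlap.
#'
#' @param exons Exon table rows for a single transcript.
#' @param annotation An `annotation_set` from [build_annotation_set()].
#' @param strand_mode `"agnostic"` (default): overlap against the
#'   strand-collapsed union. `"same"`: overlap only against annotated exons on
#'   the transcript's own strand; transcripts of unknown strand fall back to
#'   the strand-agnostic union.
#' @return Number of overlapping bases (integer).
#' @export
exonic_overlap <- function(exons, annotation,
                           strand_mode = c("agnostic", "same")) {
  strand_mode <- match.arg(strand_mode)
  nt <- novelty_scores(exons, annotation, strand_mode = strand_mode)
  if (nrow(nt) != 1L) stop("exonic_overlap expects exons of a single transcript")
  nt$overlap_bases
}

#' Novelty score of a transcript
#'
#' `NS = (1 - overlap_bases / exonic_length) * 100`: the percentage of the
#' transcript's exonic length not covered by any annotated exon. 0 means fully
#' annotated coverage, 100 means no overlap with the annotation at all.
#'
#' @inheritParams exonic_overlap
#' @param length_mode `"exonic"` (default): the denominator is the summed
#'   exon length (mature transcript length). `"span"`: the denominator is the
#'   genomic span `max(end) - min(start)` and the overlap is computed over the
#'   span, for sensitivity analysis.
#' @return Novelty score in `[0, 100]`.
#' @export
novelty_score <- function(exons, annotation,
                          strand_mode = c("agnostic", "same"),
                          length_mode = c("exonic", "span")) {
  nt <- novelty_scores(exons, annotation, strand_mode = match.arg(strand_mode),
                       length_mode = match.arg(length_mode))
  if (nrow(nt) != 1L) stop("novelty_score expects exons of a single transcript")
  nt$novelty_score
}

#' Novelty table: score and classify every assembled transcript
#'
#' For each transcript, computes exonic length, annotated overlap, the novelty
#' score NS and the class label:
#' * `known` -- the exon chain exactly matches a reference transcript's chain
#'   (chromosome and every exon boundary equal, strands compatible). This is
#'   stricter than NS = 0, which a contained fragment can also achieve; such
#'   fragments are labelled PNT.
#' * `PNT` (partially novel) -- NS < 70.
#' * `CNT` (completely novel) -- NS >= 70 (the boundary belongs to CNT).
#'
#' @param exons Exon table of assembled transcripts (possibly many).
#' @param annotation An `annotation_set`.
#' @param strand_mode,length_mode See [novelty_score()].
#' @param cnt_cutoff Class boundary on NS, default 70.
#' @return `data.frame` with one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `exonic_length`, `overlap_bases`,
#'   `novelty_score`, `class`.
#' @export
novelty_scores <- function(exons, annotation,
                           strand_mode = c("agnostic", "same"),
                           length_mode = c("exonic", "span"),
                           cnt_cutoff = 70) {
  strand_mode <- match.arg(strand_mode)
  length_mode <- match.arg(length_mode)
  stopifnot(inherits(annotation, "annotation_set"))
  validate_exon_table(exons)
  if (nrow(exons) == 0L) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      exonic_length = integer(), overlap_bases = integer(),
                      novelty_score = double(), class = character(),
                      stringsAsFactors = FALSE))
  }
  ids <- unique(exons$transcript_id)

  if (length_mode == "span") {
    s <- tapply(exons$start, exons$transcript_id, min)[ids]
    e <- tapply(exons$end, exons$transcript_id, max)[ids]
    first <- exons[!duplicated(exons$transcript_id), , drop = FALSE]
    first <- first[match(ids, first$transcript_id), , drop = FALSE]
    units <- data.frame(transcript_id = ids, chrom = first$chrom,
                        strand = first$strand, start = as.integer(s),
                        end = as.integer(e), stringsAsFactors = FALSE)
  } else {
    units <- exons
  }

  gr <- exons_to_granges(units)
  lens <- tapply(units$end - units$start, units$transcript_id, sum)[ids]

  if (strand_mode == "same") {
    un <- annotation$union_stranded
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, un))
    ok <- as.character(GenomicRanges::strand(gr))[S4Vectors::queryHits(hits)] ==
      as.character(GenomicRanges::strand(un))[S4Vectors::subjectHits(hits)]
    # unknown-strand transcripts fall back to strand-agnostic overlap
    unk <- as.character(GenomicRanges::strand(gr))[S4Vectors::queryHits(hits)] == "*"
    hits2 <- suppressWarnings(GenomicRanges::findOverlaps(gr, annotation$union, ignore.strand = TRUE))
    keep_unk <- as.character(GenomicRanges::strand(gr))[S4Vectors::queryHits(hits2)] == "*"
    ov <- c(
      overlap_widths(gr, un, hits[ok & !unk]),
      overlap_widths(gr, annotation$union, hits2[keep_unk])
    )
    tx <- c(
      units$transcript_id[S4Vectors::queryHits(hits[ok & !unk])],
      units$transcript_id[S4Vectors::queryHits(hits2[keep_unk])]
    )
  } else {
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, annotation$union, ignore.strand = TRUE))
    ov <- overlap_widths(gr, annotation$union, hits)
    tx <- units$transcript_id[S4Vectors::queryHits(hits)]
  }
  ov_by_tx <- tapply(ov, tx, sum)
  overlap <- rep(0L, length(ids))
  names(overlap) <- ids
  if (length(ov_by_tx)) overlap[names(ov_by_tx)] <- as.integer(ov_by_tx)
  # stranded union pieces can double-cover a base when +/- annotations overlap;
  # cap at the transcript length (per-base counting never exceeds it)
  overlap <- pmin(overlap, as.integer(lens))

  ns <- (1 - overlap / as.numeric(lens)) * 100

  # known = exact chain match against the reference, strands compatible
  keys <- chain_keys(exons)
  keys <- keys[match(ids, keys$transcript_id), , drop = FALSE]
  ref <- annotation$chains
  m <- match(keys$chain_key, ref$chain_key)
  compatible <- !is.na(m) &
    (keys$strand == ref$strand[m] | keys$strand == "*" | ref$strand[m] == "*")
  cls <- ifelse(compatible, "known", ifelse(ns < cnt_cutoff, "PNT", "CNT"))

  first <- exons[!duplicated(exons$transcript_id), , drop = FALSE]
  first <- first[match(ids, first$transcript_id), , drop = FALSE]
  out <- data.frame(
    transcript_id = ids,
    gene_id = if ("gene_id" %in% names(first)) first$gene_id else NA_character_,
    chrom = first$chrom,
    strand = first$strand,
    exonic_length = as.integer(lens),
    overlap_bases = overlap,
    novelty_score = as.numeric(ns),
    class = cls,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

overlap_widths <- function(gr, un, hits) {
  if (length(hits) == 0L) return(integer())
  GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(gr)[S4Vectors::queryHits(hits)],
    GenomicRanges::ranges(un)[S4Vectors::subjectHits(hits)]
  ))
}

#' Classify one transcript as known / PNT / CNT
#'
#' @inheritParams exonic_overlap
#' @param cnt_cutoff NS boundary, default 70 (boundary value is CNT).
#' @return One of `"known"`, `"PNT"`, `"CNT"`.
#' @export
classify_transcript <- function(exons, annotation, cnt_cutoff = 70) {
  nt <- novelty_scores(exons, annotation, cnt_cutoff = cnt_cutoff)
  if (nrow(nt) != 1L) stop("classify_transcript expects a single transcript")
  nt$class
}

#' Write a novelty table as TSV
#'
#' @param novelty Result of [novelty_scores()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_novelty <- function(novelty, path) {
  data.table::fwrite(novelty, path, sep = "\t")
  invisible(path)
}
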