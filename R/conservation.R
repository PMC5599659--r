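#' Mean conservation score over one interval
#'
#' Arithmetic mean of the per-base scores stored in the track over the bases
#' of the interval that have data. Returns `NA` (the no-data marker) when no
#' base of the interval is scored.
#'
#' @param track A `conservation_track`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Mean score in `[0, 1]`, or `NA` if the interval has no data.
#' @export
exon_mean_score <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "conservation_track"), start >= 0, end > start)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, track$gr))
  if (length(hits) == 0L) return(NA_real_)
  w <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(q)[S4Vectors::queryHits(hits)],
    GenomicRanges::ranges(track$gr)[S4Vectors::subjectHits(hits)]
  ))
  v <- track$gr$value[S4Vectors::subjectHits(hits)]
  sum(w * v) / sum(w)
}

#' Per-transcript conservation scores
#'
#' Aggregates a per-base conservation track in two steps: each exon gets the
#' arithmetic mean of its per-base scores; each transcript gets the
#' *unweighted* mean of its exon means (so a short exon counts as much as a
#' long one). Exons entirely without data are excluded from the transcript
#' mean rather than imputed as zero -- imputing zero would bias transcripts in
#' sparsely scored regions -- and the fraction of exonic bases with data is
#' reported as `covered_fraction` so users can filter on it.
#'
#' @param exons Exon table (one or many transcripts).
#' @param track A `conservation_track`.
#' @param weighted If `TRUE`, exon means are combined weighted by exon length
#'   (equivalent to a plain mean over all scored exonic bases) instead of the
#'   default unweighted exon mean.
#' @return `data.frame` with one row per transcript: `transcript_id`,
#'   `transcript_score` (`NA` when no exon has data), `covered_fraction`,
#'   `n_exons`, `n_exons_scored`.
#' @export
transcript_conservation <- function(exons, track, weighted = FALSE) {
  stopifnot(inherits(track, "conservation_track"))
  validate_exon_table(exons)
  ids <- unique(exons$transcript_id)
  if (nrow(exons) == 0L) {
    return(data.frame(transcript_id = character(), transcript_score = double(),
                      covered_fraction = double(), n_exons = integer(),
                      n_exons_scored = integer(), stringsAsFactors = FALSE))
  }
  gr <- exons_to_granges(exons)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr, track$gr))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  w <- if (length(hits)) {
    GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(gr)[qh], GenomicRanges::ranges(track$gr)[sh]))
  } else integer()
  v <- track$gr$value[sh]

  n_ex <- nrow(exons)
  wsum <- rep(0, n_ex)
  vsum <- rep(0, n_ex)
  if (length(hits)) {
    agg_w <- tapply(w, qh, sum)
    agg_v <- tapply(w * v, qh, sum)
    idx <- as.integer(names(agg_w))
    wsum[idx] <- agg_w
    vsum[idx] <- agg_v
  }
  exon_mean <- ifelse(wsum > 0, vsum / wsum, NA_real_)
  exon_len <- exons$end - exons$start

  per_tx <- function(f, x) as.numeric(tapply(x, exons$transcript_id, f)[ids])
  if (weighted) {
    num <- per_tx(sum, ifelse(is.na(exon_mean), 0, exon_mean * exon_len))
    den <- per_tx(sum, ifelse(is.na(exon_mean), 0, exon_len))
    score <- ifelse(den > 0, num / den, NA_real_)
  } else {
    score <- as.numeric(tapply(exon_mean, exons$transcript_id,
                               function(x) {
                                 x <- x[!is.na(x)]
                                 if (length(x)) mean(x) else NA_real_
                               })[ids])
  }
  data.frame(
    transcript_id = ids,
    transcript_score = score,
    covered_fraction = per_tx(sum, wsum) / per_tx(sum, exon_len),
    n_exons = as.integer(per_tx(length, exon_len)),
    n_exons_scored = as.integer(per_tx(sum, !is.na(exon_mean))),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write a conservation table as TSV
#'
#' @param conservation Result of [transcript_conservation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation <- function(conservation, path) {
  data.table::fwrite(conservation, path, sep = "\t")
  invisible(path)
}
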