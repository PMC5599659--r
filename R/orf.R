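# Stop codons of the standard genetic code.
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find open reading frames in six frames
#'
#' Scans all six reading frames (three offsets on the given sequence, three on
#' its reverse complement). Within a frame, an ORF opens at the first start
#' codon after the previous stop and closes at the next in-frame stop
#' (one ORF per stop-delimited segment; set `all_starts = TRUE` to also emit
#' nested ORFs from later starts). Codons containing `N` never match starts or
#' stops. Offsets are 0-based half-open on the scanned strand's sequence
#' (i.e. on the reverse complement for `-` hits); `end_offset` excludes the
#' stop codon and `length_codons` includes the start codon.
#'
#' @param seq A single DNA sequence (character, `A/C/G/T/N`).
#' @param start_codons Allowed start codons. Default is the canonical `ATG`
#'   plus the near-cognate NTG family `CTG`, `GTG`, `TTG`.
#' @param min_codons Minimum ORF length in codons (start included, stop
#'   excluded), default 25.
#' @param require_stop If `TRUE` (default) an ORF must end at a stop codon;
#'   open-ended runs at the 3' end are discarded.
#' @param all_starts Emit one ORF per start codon instead of only the first
#'   start per stop-delimited segment.
#' @param transcript_id Optional id recorded in the result.
#' @return `data.frame`: `transcript_id`, `strand`, `frame` (0/1/2),
#'   `start_offset`, `end_offset`, `start_codon`, `length_codons`.
#' @export
find_orfs <- function(seq, start_codons = c("ATG", "CTG", "GTG", "TTG"),
                      min_codons = 25L, require_stop = TRUE,
                      all_starts = FALSE, transcript_id = NA_character_) {
  stopifnot(length(seq) == 1L, min_codons >= 1L)
  seq <- toupper(seq)
  hits <- list()
  for (str in c("+", "-")) {
    s <- if (str == "+") seq else revcomp(seq)
    L <- nchar(s)
    for (frame in 0:2) {
      n_codons <- (L - frame) %/% 3L
      if (n_codons < 1L) next
      starts_at <- frame + 3L * (seq_len(n_codons) - 1L) + 1L  # 1-based
      codons <- substring(s, starts_at, starts_at + 2L)
      has_n <- grepl("N", codons, fixed = TRUE)
      is_stop <- codons %in% STOP_CODONS & !has_n
      is_start <- codons %in% start_codons & !has_n
      stop_idx <- which(is_stop)
      # segment boundaries: runs between consecutive stops
      seg_open <- c(1L, stop_idx + 1L)
      seg_close_stop <- c(stop_idx, NA_integer_)  # NA = open-ended at 3' end
      for (k in seq_along(seg_open)) {
        a <- seg_open[k]
        stop_pos <- seg_close_stop[k]
        b <- if (is.na(stop_pos)) n_codons else stop_pos - 1L
        if (a > b) next
        if (is.na(stop_pos) && require_stop) next
        cand <- which(is_start[a:b]) + a - 1L
        if (!length(cand)) next
        if (!all_starts) cand <- cand[1L]
        end_codon <- if (is.na(stop_pos)) b + 1L else stop_pos
        for (i in cand) {
          len <- end_codon - i
          if (len < min_codons) next
          hits[[length(hits) + 1L]] <- data.frame(
            transcript_id = transcript_id, strand = str, frame = frame,
            start_offset = frame + 3L * (i - 1L),
            end_offset = frame + 3L * (end_codon - 1L),
            start_codon = codons[i], length_codons = len,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(transcript_id = character(), strand = character(),
                      frame = integer(), start_offset = integer(),
                      end_offset = integer(), start_codon = character(),
                      length_codons = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Reverse complement of a DNA string
#'
#' @param seq Character scalar over `A/C/G/T/N` (case preserved as upper).
#' @return Reverse-complemented sequence.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Longest ORF among hits of one transcript
#'
#' Ties on length are broken deterministically: `+` strand before `-`, lower
#' frame first, lower start offset first.
#'
#' @param hits `data.frame` from [find_orfs()].
#' @return The winning row, or `NULL` when `hits` is empty.
#' @export
longest_orf <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  ord <- order(-hits$length_codons,
               match(hits$strand, c("+", "-")),
               hits$frame, hits$start_offset)
  hits[ord[1L], , drop = FALSE]
}

#' ORF table for a set of sequences
#'
#' Runs [find_orfs()] on every sequence and optionally keeps only the longest
#' ORF per transcript.
#'
#' @param seqs Named character vector (e.g. from [read_fasta()]).
#' @param ... Passed to [find_orfs()].
#' @param longest_only Keep only the longest hit per transcript.
#' @return Combined `data.frame` of hits.
#' @export
orf_table <- function(seqs, ..., longest_only = FALSE) {
  res <- lapply(names(seqs), function(id) {
    h <- find_orfs(seqs[[id]], ..., transcript_id = id)
    if (longest_only) h <- longest_orf(h)
    h
  })
  res <- Filter(function(x) !is.null(x) && nrow(x) > 0L, res)
  if (!length(res)) {
    return(find_orfs("", min_codons = 1L)[0, ])
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
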