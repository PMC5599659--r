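#' Read exon models from a GTF file
#'
#' Parses an Ensembl-dialect GTF (via [rtracklayer::import()]) and returns the
#' exon features as a transcript-model table in the package's internal
#' coordinate convention: 0-based, half-open intervals, so that
#' `length = end - start`. GTF coordinates are 1-based inclusive; the internal
#' start is therefore `GTF start - 1`. Strand `"."` is preserved as the
#' first-class unknown value `"*"`, never coerced to `"+"`.
#'
#' @param path Path to a GTF file with `exon` features carrying `transcript_id`
#'   and `gene_id` attributes.
#' @param source_label Either `"assembled"` or `"reference"`; recorded in the
#'   `source` column of the result.
#' @return A `data.frame` with one row per exon and columns `transcript_id`,
#'   `gene_id`, `chrom`, `strand` (`"+"`, `"-"` or `"*"`), `start`, `end`
#'   (0-based half-open) and `source`. Exons are sorted by start within each
#'   transcript.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "toy", "exon", 11, 20, ".", "+", ".",
#'   'gene_id "g1"; transcript_id "t1";', sep = "\t"), gtf)
#' read_gtf(gtf, "reference")
#' @export
read_gtf <- function(path, source_label = c("assembled", "reference")) {
  source_label <- match.arg(source_label)
  if (!file.exists(path)) stop("GTF file not found: ", path)
  if (file.size(path) == 0L) return(empty_exon_table(source_label))
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0L) return(empty_exon_table(source_label))
  type <- as.character(gr$type)
  gr <- gr[type == "exon"]
  if (length(gr) == 0L) return(empty_exon_table(source_label))
  tid <- gr$transcript_id
  if (is.null(tid) || any(is.na(tid)) || any(!nzchar(tid))) {
    stop("GTF rejected: exon feature(s) missing transcript_id attribute in ", path)
  }
  tid <- as.character(tid)
  gid <- gr$gene_id
  if (is.null(gid)) gid <- rep(NA_character_, length(gr))
  gid <- as.character(gid)
  ex <- data.frame(
    transcript_id = tid,
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    source = source_label,
    stringsAsFactors = FALSE
  )
  ex <- ex[order(ex$transcript_id, ex$start, ex$end), , drop = FALSE]
  rownames(ex) <- NULL
  validate_exon_table(ex)
  ex
}

empty_exon_table <- function(source_label = "assembled") {
  data.frame(
    transcript_id = character(), gene_id = character(), chrom = character(),
    strand = character(), start = integer(), end = integer(),
    source = source_label[0], stringsAsFactors = FALSE
  )
}

#' Validate a transcript-model exon table
#'
#' Checks the invariants of the internal exon representation: strictly positive
#' interval lengths (`0 <= start < end`), one chromosome and strand per
#' transcript, and pairwise non-overlapping exons sorted by start.
#'
#' @param exons Exon table as returned by [read_gtf()].
#' @return The table, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_exon_table <- function(exons) {
  req <- c("transcript_id", "chrom", "strand", "start", "end")
  miss <- setdiff(req, names(exons))
  if (length(miss)) stop("exon table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(exons) == 0L) return(invisible(exons))
  if (any(exons$start < 0L)) stop("exon start < 0")
  if (any(exons$end <= exons$start)) stop("exon with non-positive length (end <= start)")
  if (!all(exons$strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'")
  }
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in by_tx) {
    if (length(unique(exons$chrom[idx])) != 1L) {
      stop("transcript ", exons$transcript_id[idx[1L]], " spans multiple chromosomes")
    }
    s <- exons$start[idx]; e <- exons$end[idx]
    o <- order(s)
    if (length(idx) > 1L && any(e[o][-length(idx)] > s[o][-1L])) {
      stop("transcript ", exons$transcript_id[idx[1L]], " has overlapping exons")
    }
  }
  invisible(exons)
}

#' Write transcript models to GTF
#'
#' Emits `exon` features in 1-based inclusive GTF coordinates (internal
#' 0-based half-open starts are shifted by +1). Unknown strand is written
#' as `"."`. Reading the file back with [read_gtf()] reproduces the input
#' coordinates exactly.
#'
#' @param exons Exon table (see [read_gtf()]).
#' @param path Output path.
#' @param feature_source Value for GTF column 2.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(exons, path, feature_source = "novelscope") {
  validate_exon_table(exons)
  strand <- ifelse(exons$strand == "*", ".", exons$strand)
  gid <- if ("gene_id" %in% names(exons)) exons$gene_id else exons$transcript_id
  lines <- sprintf(
    "%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    exons$chrom, feature_source, exons$start + 1L, exons$end, strand,
    gid, exons$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Build an annotation set from reference exon models
#'
#' Collects reference transcript models into the container used for novelty
#' scoring: the strand-agnostic merged exonic union, a strand-partitioned
#' union, and the set of exact exon-chain keys used to recognize known
#' transcripts.
#'
#' @param exons Reference exon table (all rows `source == "reference"`; an
#'   empty table yields a valid empty annotation set).
#' @return An object of class `annotation_set` with elements `exons`,
#'   `union` (strand-agnostic `GRanges`, disjoint and sorted), `union_stranded`
#'   (`GRanges` reduced per strand) and `chains` (`data.frame` of per-transcript
#'   chain keys and strands).
#' @export
build_annotation_set <- function(exons) {
  validate_exon_table(exons)
  if (nrow(exons) > 0L && "source" %in% names(exons) &&
      !all(exons$source == "reference")) {
    stop("build_annotation_set expects reference models only")
  }
  gr <- exons_to_granges(exons)
  un <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  un <- GenomicRanges::sort(un)
  uns <- GenomicRanges::reduce(gr)  # per-strand
  chains <- chain_keys(exons)
  structure(
    list(exons = exons, union = un, union_stranded = uns, chains = chains),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:",
      length(unique(x$exons$transcript_id)), "transcripts,",
      length(x$union), "union intervals,",
      sum(GenomicRanges::width(x$union)), "union bases\n")
  invisible(x)
}

# GRanges from internal 0-based half-open exon rows (GRanges is 1-based incl.)
exons_to_granges <- function(exons) {
  if (nrow(exons) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
    strand = exons$strand,
    transcript_id = exons$transcript_id
  )
}

# one key per transcript: chrom + all exon boundaries
chain_keys <- function(exons) {
  if (nrow(exons) == 0L) {
    return(data.frame(transcript_id = character(), chain_key = character(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  ord <- order(exons$transcript_id, exons$start)
  ex <- exons[ord, , drop = FALSE]
  sp <- split(seq_len(nrow(ex)), ex$transcript_id)
  keys <- vapply(sp, function(idx) {
    paste0(ex$chrom[idx[1L]], ":",
           paste(ex$start[idx], ex$end[idx], sep = "-", collapse = ","))
  }, character(1L))
  strands <- vapply(sp, function(idx) ex$strand[idx[1L]], character(1L))
  data.frame(transcript_id = names(sp), chain_key = unname(keys),
             strand = unname(strands), stringsAsFactors = FALSE)
}

#' Total exonic length per transcript
#'
#' @param exons Exon table.
#' @return Named integer vector of summed exon lengths (bases) per transcript.
#' @export
exonic_lengths <- function(exons) {
  if (nrow(exons) == 0L) return(stats::setNames(integer(), character()))
  tapply(exons$end - exons$start, exons$transcript_id, sum)[
    unique(exons$transcript_id)]
}
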