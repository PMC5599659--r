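#' Read a per-base conservation track from bedGraph
#'
#' bedGraph records are 0-based half-open with a value column; every base in a
#' record maps to its value. Records whose value falls outside `[0, 1]` are
#' rejected with a warning (the count of rejected records is reported).
#' Where records overlap, the later record in the file wins; this last-wins
#' rule is deterministic and is the only overlap resolution offered.
#'
#' @param path Path to a 4-column bedGraph (chrom, start, end, value); track
#'   definition lines and `#` comments are ignored.
#' @return A `conservation_track` object: a disjoint, sorted interval table
#'   (`chrom`, `start`, `end`, `value`) with an internal `GRanges` index.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  dt <- data.table::fread(
    path, header = FALSE, sep = "\t", skip = 0L, fill = TRUE,
    col.names = c("chrom", "start", "end", "value")[1:4],
    colClasses = list(character = 1L)
  )
  dt <- dt[!grepl("^(track|browser|#)", dt$chrom), ]
  if (nrow(dt) == 0L) {
    return(conservation_track(data.frame(chrom = character(), start = integer(),
                                         end = integer(), value = double())))
  }
  dt$start <- as.integer(dt$start)
  dt$end <- as.integer(dt$end)
  dt$value <- as.numeric(dt$value)
  bad <- is.na(dt$value) | dt$value < 0 | dt$value > 1
  if (any(bad)) {
    warning(sum(bad), " bedGraph record(s) with value outside [0,1] rejected")
    dt <- dt[!bad, ]
  }
  conservation_track(as.data.frame(dt))
}

#' Construct a conservation track from scored intervals
#'
#' Intervals are 0-based half-open with a score in `[0, 1]`. Overlaps are
#' resolved last-record-wins (input order is significant), producing a
#' disjoint, sorted representation.
#'
#' @param intervals `data.frame` with columns `chrom`, `start`, `end`, `value`.
#' @return A `conservation_track` object.
#' @export
conservation_track <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(intervals)))
  if (nrow(intervals) == 0L) {
    tr <- intervals[, c("chrom", "start", "end", "value")]
    return(structure(list(intervals = tr, gr = GenomicRanges::GRanges()),
                     class = "conservation_track"))
  }
  if (any(intervals$value < 0 | intervals$value > 1)) {
    stop("conservation values must lie in [0, 1]")
  }
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start + 1L, intervals$end)
  )
  dj <- GenomicRanges::disjoin(gr)
  hits <- GenomicRanges::findOverlaps(dj, gr)
  # last record wins: take the highest input index covering each disjoint bin
  winner <- tapply(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits), max)
  dj <- dj[as.integer(names(winner))]
  val <- intervals$value[as.integer(winner)]
  ord <- GenomicRanges::order(dj)
  dj <- dj[ord]
  val <- val[ord]
  tr <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(dj)),
    start = GenomicRanges::start(dj) - 1L,
    end = GenomicRanges::end(dj),
    value = val,
    stringsAsFactors = FALSE
  )
  dj$value <- val
  structure(list(intervals = tr, gr = dj), class = "conservation_track")
}

#' @export
print.conservation_track <- function(x, ...) {
  cat("conservation_track:", nrow(x$intervals), "runs,",
      sum(GenomicRanges::width(x$gr)), "bases covered\n")
  invisible(x)
}

#' Write a conservation track as bedGraph
#'
#' @param track A `conservation_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "conservation_track"))
  iv <- track$intervals
  lines <- sprintf("%s\t%d\t%d\t%s", iv$chrom, iv$start, iv$end,
                   formatC(iv$value, format = "fg", digits = 6))
  writeLines(lines, path)
  invisible(path)
}

#' Write BED records
#'
#' Writes 0-based half-open BED6 (tab-separated, no header). Unknown strand is
#' written as `"."`.
#'
#' @param records `data.frame` with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(records)))
  name <- if ("name" %in% names(records)) records$name else "."
  score <- if ("score" %in% names(records)) records$score else 0L
  strand <- if ("strand" %in% names(records)) {
    ifelse(records$strand == "*", ".", records$strand)
  } else "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   records$chrom, as.integer(records$start),
                   as.integer(records$end), name, score, strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read BED records
#'
#' @param path Path to a BED3+ file.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (missing columns filled with defaults; `"."` strand becomes `"*"`).
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1L))
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  names(dt)[seq_len(min(ncol(dt), 6L))] <- cols[seq_len(min(ncol(dt), 6L))]
  df <- as.data.frame(dt)
  if (!"name" %in% names(df)) df$name <- "."
  if (!"score" %in% names(df)) df$score <- 0
  if (!"strand" %in% names(df)) df$strand <- "."
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$strand <- ifelse(df$strand == ".", "*", df$strand)
  df[, cols]
}
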