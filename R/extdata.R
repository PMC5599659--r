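#' Path to a bundled example data file
#'
#' The package ships small plain-text fixtures: the RNA-seq sample metadata
#' table of the lens developmental series, the published high-confidence CNT
#' table, genome-wide summary counts, and a table of skipped-exon PSI values
#' across stages.
#'
#' @param name File name under `extdata`; with no argument, lists the
#'   available files.
#' @return Full path (or a character vector of file names).
#' @export
ns_example <- function(name = NULL) {
  if (is.null(name)) {
    return(dir(system.file("extdata", package = "novelscope")))
  }
  path <- system.file("extdata", name, package = "novelscope")
  if (!nzchar(path)) stop("no bundled file called ", name)
  path
}

#' Sequencing-run metadata with recomputed base counts
#'
#' Reads the bundled sample metadata table and recomputes the total base
#' count of every run as `reads x mate_count x read_length` (mate count 2 for
#' paired-end runs, 1 for single-end), for comparison with the reported
#' `base_count` column.
#'
#' @param path Metadata TSV; defaults to the bundled table.
#' @return The table with extra columns `mate_count` and
#'   `computed_base_count`.
#' @export
read_run_metadata <- function(path = ns_example("lens_rnaseq_samples.tsv")) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  df$mate_count <- ifelse(df$read_type == "PE", 2L, 1L)
  df$computed_base_count <- as.numeric(df$n_reads) * df$mate_count * df$read_length
  df
}

#' Published high-confidence CNT records as filter input
#'
#' Reads the bundled high-confidence CNT table (coordinates, printed length,
#' strand, conservation and novelty scores, and which of the two selection
#' rules each row satisfied) into the record format used by [apply_filter()],
#' with the interval length recomputed as `end - start` from the printed
#' coordinates.
#'
#' @param path Table TSV; defaults to the bundled table.
#' @return `data.frame` with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `length` (printed), `computed_length` (`end - start`),
#'   `strand`, `ps`, `ns`, `class`, `filter_set`.
#' @export
read_highconf_records <- function(path = ns_example("highconf_cnt_table.tsv")) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  data.frame(
    transcript_id = df$transcript_id,
    gene_id = df$gene_id,
    chrom = df$chrom,
    start = df$start,
    end = df$end,
    length = df$length_bp,
    computed_length = df$end - df$start,
    strand = df$strand,
    ps = df$phastcons,
    ns = df$novelty_score,
    class = "CNT",
    filter_set = df$filter_set,
    stringsAsFactors = FALSE
  )
}

#' Genome-scale summary counts
#'
#' @param path Counts TSV; defaults to the bundled table.
#' @return Named numeric vector.
#' @export
read_summary_counts <- function(path = ns_example("lens_summary_counts.tsv")) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  stats::setNames(as.numeric(df$value), df$metric)
}

#' Bundled skipped-exon PSI table as a stage matrix
#'
#' @param path PSI TSV; defaults to the bundled table.
#' @return List with `events` (geometry `data.frame` usable by
#'   [events_to_bed()]) and `stage_psi` (matrix events x stages, `NA` cells
#'   allowed).
#' @export
read_se_psi_table <- function(path = ns_example("skipped_exon_psi.tsv")) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA"))
  stage_cols <- setdiff(names(df), c("exon_id", "chrom", "start", "end",
                                     "strand", "transcript_id", "gene"))
  m <- as.matrix(df[, stage_cols, drop = FALSE])
  rownames(m) <- df$exon_id
  events <- data.frame(
    event_id = df$exon_id, type = "SE", gene = df$gene,
    chrom = df$chrom, start = df$start, end = df$end, strand = df$strand,
    stringsAsFactors = FALSE
  )
  list(events = events, stage_psi = m)
}
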