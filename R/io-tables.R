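#' Read a transcript x sample TPM matrix with its sample design
#'
#' The expression TSV has a `transcript_id` column followed by one column per
#' sample; the design TSV maps each sample to a developmental stage and a
#' replicate number. Every sample column in the matrix must appear exactly
#' once in the design, otherwise the pair is rejected.
#'
#' @param path Expression TSV path.
#' @param design_path Design TSV path (columns `sample`, `stage`, `replicate`).
#' @param excluded_stages Stages dropped by default in downstream stage
#'   summaries (kept in the object; see [stage_means()]). Default `"E15.5"`,
#'   the stage profiled on a different platform than the rest of the series.
#' @return An `expression_set`: list with `tpm` (numeric matrix, transcripts x
#'   samples), `design` (`data.frame`), `stages` (ordered unique stages) and
#'   `excluded_stages`.
#' @export
read_expression <- function(path, design_path, excluded_stages = "E15.5") {
  mat <- data.table::fread(path, header = TRUE, sep = "\t")
  if (!"transcript_id" %in% names(mat)) {
    stop("expression matrix must have a transcript_id column")
  }
  ids <- mat$transcript_id
  if (anyDuplicated(ids)) stop("duplicate transcript_id rows in expression matrix")
  m <- as.matrix(mat[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  design <- read_design(design_path)
  expression_set(m, design, excluded_stages = excluded_stages)
}

#' Read a sample design table
#'
#' @param path TSV with columns `sample`, `stage`, `replicate`.
#' @return `data.frame`.
#' @export
read_design <- function(path) {
  d <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  miss <- setdiff(c("sample", "stage", "replicate"), names(d))
  if (length(miss)) stop("design table missing columns: ", paste(miss, collapse = ", "))
  d$sample <- as.character(d$sample)
  d$stage <- as.character(d$stage)
  d
}

#' Assemble an expression set from a matrix and design
#'
#' @param tpm Numeric matrix (transcripts x samples), non-negative, with
#'   unique row and column names.
#' @param design Design `data.frame` (`sample`, `stage`, `replicate`).
#' @param excluded_stages Character vector of stages excluded by default from
#'   stage summaries.
#' @return An `expression_set` object.
#' @export
expression_set <- function(tpm, design, excluded_stages = "E15.5") {
  stopifnot(is.matrix(tpm))
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  if (anyDuplicated(rownames(tpm))) stop("duplicate transcript ids")
  if (anyDuplicated(colnames(tpm))) stop("duplicate sample names")
  missing_in_design <- setdiff(colnames(tpm), design$sample)
  if (length(missing_in_design)) {
    stop("sample(s) in matrix missing from design: ",
         paste(missing_in_design, collapse = ", "))
  }
  if (anyDuplicated(design$sample)) stop("duplicate samples in design")
  design <- design[match(colnames(tpm), design$sample), , drop = FALSE]
  stages <- unique(design$stage)
  structure(
    list(tpm = tpm, design = design, stages = stages,
         excluded_stages = intersect(excluded_stages, stages)),
    class = "expression_set"
  )
}

#' @export
print.expression_set <- function(x, ...) {
  cat("expression_set:", nrow(x$tpm), "transcripts x", ncol(x$tpm), "samples;",
      "stages:", paste(x$stages, collapse = ", "), "\n")
  if (length(x$excluded_stages)) {
    cat("  excluded by default:", paste(x$excluded_stages, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write an expression matrix (and optionally its design) as TSV
#'
#' Round-trips bit-identically through [read_expression()].
#'
#' @param eset An `expression_set`.
#' @param path Matrix output path.
#' @param design_path Optional design output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(eset, path, design_path = NULL) {
  stopifnot(inherits(eset, "expression_set"))
  dt <- data.table::data.table(transcript_id = rownames(eset$tpm))
  for (s in colnames(eset$tpm)) dt[[s]] <- eset$tpm[, s]
  data.table::fwrite(dt, path, sep = "\t")
  if (!is.null(design_path)) {
    data.table::fwrite(eset$design, design_path, sep = "\t")
  }
  invisible(path)
}

#' Read transcript sequences from FASTA
#'
#' Bases are normalized to uppercase on read.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
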