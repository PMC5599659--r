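#' Define a compound high-confidence filter
#'
#' A filter is a conjunction of predicates over per-transcript records
#' carrying exonic length, conservation score (PS), novelty score (NS), class
#' and stage-wise mean TPM. Comparison strictness follows the conventions used
#' for the published high-confidence transcript lists: length bounds are
#' inclusive, the PS cut is strict (`>`), the stage-wise TPM cut is strict
#' (`>`), and `required_ns` is a lower bound on NS (so 100 demands fully novel
#' transcripts, since NS cannot exceed 100).
#'
#' @param name Filter name (used in output file names).
#' @param min_length,max_length Inclusive bounds on transcript length (bases);
#'   `NULL` disables a bound.
#' @param min_ps Strict lower bound on the conservation score; `NULL` disables.
#' @param required_ns Lower bound on the novelty score; `NULL` disables.
#' @param required_class Keep only this class (`"known"`, `"PNT"`, `"CNT"`);
#'   `NULL` disables.
#' @param stage_tpm_threshold Per-stage mean TPM above which a stage counts as
#'   "expressed" for this filter (strict `>`). 0 means any positive expression.
#' @param min_stages_expressed,max_stages_expressed Bounds on the number of
#'   expressed stages; `NULL` disables.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(name = "custom",
                        min_length = NULL, max_length = NULL,
                        min_ps = NULL, required_ns = NULL,
                        required_class = NULL,
                        stage_tpm_threshold = 0,
                        min_stages_expressed = NULL,
                        max_stages_expressed = NULL) {
  if (!is.null(min_length) && !is.null(max_length) && min_length > max_length) {
    stop("min_length > max_length")
  }
  if (!is.null(min_ps) && (min_ps < 0 || min_ps > 1)) stop("min_ps must be in [0,1]")
  structure(
    list(name = name, min_length = min_length, max_length = max_length,
         min_ps = min_ps, required_ns = required_ns,
         required_class = required_class,
         stage_tpm_threshold = stage_tpm_threshold,
         min_stages_expressed = min_stages_expressed,
         max_stages_expressed = max_stages_expressed),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  on <- Filter(Negate(is.null), x[-1])
  cat("filter_spec '", x$name, "': ",
      paste(names(on), unlist(on), sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Built-in high-confidence filter catalog
#'
#' Named filters reproducing the published selection rules:
#' * `cnt_broad` -- fully novel (NS = 100), 300-10000 bases, PS > 0.95,
#'   mean TPM > 5.0 in at least four developmental stages (broadly expressed
#'   candidates).
#' * `cnt_specific` -- same length/PS/NS cuts, no TPM floor, expressed
#'   (TPM > 0) in at most two stages (stage-specific candidates; most
#'   transcripts in this category are poorly expressed).
#' * `pnt_conserved` -- PNTs with PS > 0.8 (conserved PNT gene set).
#' * `cnt_conserved_expressed` -- CNTs with PS > 0.8 expressed (TPM > 0) in at
#'   least one stage (the heatmap set).
#' * `cnt_highly_conserved` -- CNTs with PS > 0.76, i.e. above the PNT median
#'   conservation (the "highly conserved CNT" definition).
#'
#' @return Named list of `filter_spec` objects.
#' @export
builtin_specs <- function() {
  list(
    cnt_broad = filter_spec(
      "cnt_broad", min_length = 300, max_length = 10000, min_ps = 0.95,
      required_ns = 100, required_class = "CNT",
      stage_tpm_threshold = 5, min_stages_expressed = 4
    ),
    cnt_specific = filter_spec(
      "cnt_specific", min_length = 300, max_length = 10000, min_ps = 0.95,
      required_ns = 100, required_class = "CNT",
      stage_tpm_threshold = 0, max_stages_expressed = 2
    ),
    pnt_conserved = filter_spec(
      "pnt_conserved", min_ps = 0.8, required_class = "PNT"
    ),
    cnt_conserved_expressed = filter_spec(
      "cnt_conserved_expressed", min_ps = 0.8, required_class = "CNT",
      stage_tpm_threshold = 0, min_stages_expressed = 1
    ),
    cnt_highly_conserved = filter_spec(
      "cnt_highly_conserved", min_ps = 0.76, required_class = "CNT"
    )
  )
}

#' Apply a filter to per-transcript records
#'
#' A record survives iff every configured predicate passes. Records missing a
#' field required by a configured predicate are excluded -- not silently
#' dropped: they are listed, with reasons, in the `excluded` attribute of the
#' result.
#'
#' @param records `data.frame` with columns `transcript_id`, `length`, `ps`,
#'   `ns`, `class` (only those referenced by the configured predicates are
#'   required).
#' @param spec A `filter_spec`.
#' @param sm Optional stage-mean TPM matrix (rows matched to
#'   `records$transcript_id`) for the stage-count predicates.
#' @return The surviving rows of `records`, with attribute `excluded`
#'   (`data.frame` of `transcript_id`, `reason` for records dropped because a
#'   required field was missing).
#' @export
apply_filter <- function(records, spec, sm = NULL) {
  stopifnot(inherits(spec, "filter_spec"))
  n <- nrow(records)
  keep <- rep(TRUE, n)
  excluded <- list()
  need <- function(col, pred_name) {
    if (!col %in% names(records)) {
      return(rep(NA, n))
    }
    records[[col]]
  }
  drop_missing <- function(vals, pred_name) {
    bad <- is.na(vals) & keep
    if (any(bad)) {
      excluded[[length(excluded) + 1L]] <<- data.frame(
        transcript_id = records$transcript_id[bad],
        reason = paste0("missing field for predicate ", pred_name),
        stringsAsFactors = FALSE
      )
      keep[bad] <<- FALSE
    }
    vals
  }

  if (!is.null(spec$min_length) || !is.null(spec$max_length)) {
    len <- drop_missing(need("length", "length"), "length")
    if (!is.null(spec$min_length)) keep <- keep & !is.na(len) & len >= spec$min_length
    if (!is.null(spec$max_length)) keep <- keep & !is.na(len) & len <= spec$max_length
  }
  if (!is.null(spec$min_ps)) {
    ps <- drop_missing(need("ps", "ps"), "ps")
    keep <- keep & !is.na(ps) & ps > spec$min_ps
  }
  if (!is.null(spec$required_ns)) {
    ns <- drop_missing(need("ns", "ns"), "ns")
    keep <- keep & !is.na(ns) & ns >= spec$required_ns
  }
  if (!is.null(spec$required_class)) {
    cls <- drop_missing(need("class", "class"), "class")
    keep <- keep & !is.na(cls) & cls == spec$required_class
  }
  if (!is.null(spec$min_stages_expressed) || !is.null(spec$max_stages_expressed)) {
    if (is.null(sm)) {
      stop("filter '", spec$name, "' needs a stage-mean matrix (sm)")
    }
    m <- match(records$transcript_id, rownames(sm))
    missing_sm <- is.na(m) & keep
    if (any(missing_sm)) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        transcript_id = records$transcript_id[missing_sm],
        reason = "missing stage expression", stringsAsFactors = FALSE)
      keep[missing_sm] <- FALSE
    }
    nst <- rep(NA_integer_, n)
    nst[!is.na(m)] <- rowSums(sm[m[!is.na(m)], , drop = FALSE] > spec$stage_tpm_threshold)
    if (!is.null(spec$min_stages_expressed)) {
      keep <- keep & !is.na(nst) & nst >= spec$min_stages_expressed
    }
    if (!is.null(spec$max_stages_expressed)) {
      keep <- keep & !is.na(nst) & nst <= spec$max_stages_expressed
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(excluded)) {
    do.call(rbind, excluded)
  } else {
    data.frame(transcript_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  out
}
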