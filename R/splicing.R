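# The five alternative-splicing event types handled throughout this module.
SPLICE_TYPES <- c("SE", "RI", "MXE", "A5SS", "A3SS")

#' Percent-spliced-in from inclusion and skip counts
#'
#' The standard length-normalized read-density estimate:
#' `psi = (I / lI) / (I / lI + S / lS)` where `I` and `S` are reads supporting
#' the inclusion and skipping isoforms and `lI`, `lS` their effective lengths
#' (number of read positions supporting each isoform). With equal effective
#' lengths this reduces exactly to `I / (I + S)`. Undefined (`NA`) when
#' `I = S = 0`.
#'
#' @param inclusion,skip Non-negative read counts (vectorized).
#' @param len_inclusion,len_skip Positive effective lengths.
#' @return psi in `[0, 1]`, or `NA` where both counts are zero.
#' @export
psi <- function(inclusion, skip, len_inclusion = 1, len_skip = 1) {
  stopifnot(all(inclusion >= 0), all(skip >= 0),
            all(len_inclusion >= 1), all(len_skip >= 1))
  di <- inclusion / len_inclusion
  ds <- skip / len_skip
  out <- di / (di + ds)
  out[inclusion == 0 & skip == 0] <- NA_real_
  out
}

#' Per-sample and per-stage PSI tables
#'
#' Computes psi per sample from junction counts, then averages replicate psi
#' values (unweighted) within each stage. Stages where no replicate has a
#' defined psi are reported as `NA`.
#'
#' @param counts `data.frame` with columns `event_id`, `sample`, `inclusion`,
#'   `skip` and optionally `len_inclusion`, `len_skip` (default 1).
#' @param design Sample design (`sample`, `stage`, `replicate`).
#' @return List with `sample_psi` (long `data.frame`) and `stage_psi` (matrix,
#'   events x stages).
#' @export
stage_psi <- function(counts, design) {
  req <- c("event_id", "sample", "inclusion", "skip")
  miss <- setdiff(req, names(counts))
  if (length(miss)) stop("counts missing columns: ", paste(miss, collapse = ", "))
  if (!"len_inclusion" %in% names(counts)) counts$len_inclusion <- 1
  if (!"len_skip" %in% names(counts)) counts$len_skip <- 1
  unknown <- setdiff(unique(counts$sample), design$sample)
  if (length(unknown)) stop("sample(s) missing from design: ",
                            paste(unknown, collapse = ", "))
  counts$psi <- psi(counts$inclusion, counts$skip,
                    counts$len_inclusion, counts$len_skip)
  counts$stage <- design$stage[match(counts$sample, design$sample)]
  events <- unique(counts$event_id)
  stages <- unique(design$stage[design$sample %in% counts$sample])
  m <- matrix(NA_real_, length(events), length(stages),
              dimnames = list(events, stages))
  agg <- stats::aggregate(psi ~ event_id + stage, data = counts,
                          FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  agg$psi[is.nan(agg$psi)] <- NA_real_
  m[cbind(match(agg$event_id, events), match(agg$stage, stages))] <- agg$psi
  list(sample_psi = counts, stage_psi = m)
}

#' Delta-PSI and fold change between two stages
#'
#' @param stage_psi_matrix Matrix from [stage_psi()].
#' @param stage_a,stage_b Stage names; delta is `psi_b - psi_a`.
#' @return `data.frame`: `event_id`, `psi_a`, `psi_b`, `delta_psi`,
#'   `fold_change` (`psi_b / psi_a`, `NA` when `psi_a` is 0 or undefined).
#' @export
delta_psi <- function(stage_psi_matrix, stage_a, stage_b) {
  stopifnot(stage_a %in% colnames(stage_psi_matrix),
            stage_b %in% colnames(stage_psi_matrix))
  pa <- stage_psi_matrix[, stage_a]
  pb <- stage_psi_matrix[, stage_b]
  data.frame(
    event_id = rownames(stage_psi_matrix),
    psi_a = pa, psi_b = pb,
    delta_psi = pb - pa,
    fold_change = ifelse(!is.na(pa) & pa > 0, pb / pa, NA_real_),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Screen events for differential splicing between two stages
#'
#' A deliberately simple screen, not a reimplementation of the hierarchical
#' replicate models used by dedicated splicing tools: per event, inclusion and
#' skip counts are pooled across replicates within each stage and compared
#' with a two-sided Fisher exact test on the 2x2 table, followed by
#' Benjamini-Hochberg correction across events. Degenerate tables (a zero
#' margin) get `p = q = 1`.
#'
#' @param counts Junction-count `data.frame` (see [stage_psi()]).
#' @param design Sample design.
#' @param stage_a,stage_b Stages to compare.
#' @param alpha_fdr Flagging threshold on the BH q-value, default 0.01.
#' @return `data.frame`: `event_id`, pooled counts, `p_value`, `q_value`,
#'   `flagged`.
#' @export
screen_events <- function(counts, design, stage_a, stage_b, alpha_fdr = 0.01) {
  counts$stage <- design$stage[match(counts$sample, design$sample)]
  sub <- counts[counts$stage %in% c(stage_a, stage_b), , drop = FALSE]
  if (nrow(sub) == 0L) stop("no counts for the requested stages")
  dt <- data.table::as.data.table(sub)
  pooled <- dt[, list(inclusion = sum(inclusion), skip = sum(skip)),
               by = list(event_id, stage)]
  events <- unique(pooled$event_id)
  get <- function(ev, st, col) {
    v <- pooled[[col]][pooled$event_id == ev & pooled$stage == st]
    if (length(v)) v else 0L
  }
  res <- do.call(rbind, lapply(events, function(ev) {
    tab <- matrix(c(get(ev, stage_a, "inclusion"), get(ev, stage_a, "skip"),
                    get(ev, stage_b, "inclusion"), get(ev, stage_b, "skip")),
                  nrow = 2L)
    p <- if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
      1
    } else {
      stats::fisher.test(tab)$p.value
    }
    data.frame(event_id = ev,
               inclusion_a = tab[1, 1], skip_a = tab[2, 1],
               inclusion_b = tab[1, 2], skip_b = tab[2, 2],
               p_value = p, stringsAsFactors = FALSE)
  }))
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$flagged <- res$q_value < alpha_fdr
  rownames(res) <- NULL
  res
}

#' Browser-track BED records for splicing events at one stage
#'
#' One BED record per event with a defined stage psi; the BED score is
#' `round(psi * 1000)` in `[0, 1000]` (browser convention for a 0-1 quantity)
#' and the name encodes `event_id|type|stage|psi`. Events with undefined psi
#' at the stage are skipped with a message.
#'
#' @param events Event table with columns `event_id`, `type`, `chrom`,
#'   `start`, `end`, `strand`.
#' @param stage_psi_matrix Matrix from [stage_psi()].
#' @param stage Stage name.
#' @return BED `data.frame` suitable for [write_bed()].
#' @export
events_to_bed <- function(events, stage_psi_matrix, stage) {
  stopifnot(stage %in% colnames(stage_psi_matrix))
  p <- stage_psi_matrix[match(events$event_id, rownames(stage_psi_matrix)), stage]
  skip <- is.na(p)
  if (any(skip)) {
    message(sum(skip), " event(s) with undefined psi at ", stage, " skipped")
  }
  ev <- events[!skip, , drop = FALSE]
  p <- p[!skip]
  data.frame(
    chrom = ev$chrom, start = as.integer(ev$start), end = as.integer(ev$end),
    name = sprintf("%s|%s|%s|%.4g", ev$event_id, ev$type, stage, p),
    score = as.integer(round(p * 1000)),
    strand = ev$strand,
    stringsAsFactors = FALSE
  )
}

#' Read a splice-event definition table
#'
#' @param path TSV with columns `event_id`, `type`, `gene`, `chrom`, `start`,
#'   `end`, `strand` (target-interval geometry; flanks optional).
#' @return `data.frame`.
#' @export
read_events <- function(path) {
  ev <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  if (!all(ev$type %in% SPLICE_TYPES)) {
    stop("unknown event type(s): ",
         paste(setdiff(unique(ev$type), SPLICE_TYPES), collapse = ", "))
  }
  ev
}

#' Read a junction-count table
#'
#' @param path TSV with columns `event_id`, `sample`, `inclusion`, `skip`,
#'   optionally `len_inclusion`, `len_skip`.
#' @return `data.frame`.
#' @export
read_junction_counts <- function(path) {
  as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
}

#' Write a stage PSI matrix as TSV (NA cells allowed)
#'
#' @param stage_psi_matrix Matrix from [stage_psi()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psi_matrix <- function(stage_psi_matrix, path) {
  dt <- data.table::data.table(event_id = rownames(stage_psi_matrix))
  for (st in colnames(stage_psi_matrix)) dt[[st]] <- stage_psi_matrix[, st]
  data.table::fwrite(dt, path, sep = "\t", na = "NA")
  invisible(path)
}
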