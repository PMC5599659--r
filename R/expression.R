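#' Per-stage mean TPM
#'
#' Averages TPM over biological replicates within each developmental stage.
#' Stages listed in the expression set's `excluded_stages` (default `E15.5`,
#' which originates from a different study and would introduce a batch effect)
#' are dropped unless `include_excluded = TRUE`.
#'
#' @param eset An `expression_set`.
#' @param include_excluded Keep the default-excluded stages.
#' @return Numeric matrix, transcripts x stages (stage order = order of first
#'   appearance in the design).
#' @export
stage_means <- function(eset, include_excluded = FALSE) {
  stopifnot(inherits(eset, "expression_set"))
  stages <- eset$stages
  if (!include_excluded) stages <- setdiff(stages, eset$excluded_stages)
  if (!length(stages)) stop("no stages left after exclusion")
  out <- vapply(stages, function(st) {
    cols <- eset$design$sample[eset$design$stage == st]
    if (!length(cols)) stop("stage with zero samples: ", st)
    rowMeans(eset$tpm[, cols, drop = FALSE])
  }, numeric(nrow(eset$tpm)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(rownames(eset$tpm), stages))
  out
}

#' Known vs novel proportions per stage
#'
#' Among transcripts whose stage-mean TPM exceeds the threshold, the fraction
#' that are known versus novel (PNT + CNT). When no transcript passes in a
#' stage the proportions are undefined and reported as `NA`.
#'
#' @param sm Stage-mean matrix from [stage_means()].
#' @param classes Named character vector (or `data.frame` with
#'   `transcript_id`/`class`) giving each transcript's class.
#' @param threshold Expression threshold (strict `>`), default 1 TPM.
#' @return `data.frame`: `stage`, `threshold`, `n_expressed`, `n_known`,
#'   `n_novel`, `pct_known`, `pct_novel`.
#' @export
class_proportions <- function(sm, classes, threshold = 1) {
  stopifnot(threshold > 0)
  classes <- as_class_vector(classes, rownames(sm))
  do.call(rbind, lapply(colnames(sm), function(st) {
    expressed <- sm[, st] > threshold
    n <- sum(expressed)
    nk <- sum(expressed & classes == "known")
    data.frame(
      stage = st, threshold = threshold, n_expressed = n,
      n_known = nk, n_novel = n - nk,
      pct_known = if (n > 0) 100 * nk / n else NA_real_,
      pct_novel = if (n > 0) 100 * (n - nk) / n else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
}

#' Known/novel proportions across a threshold sweep
#'
#' @inheritParams class_proportions
#' @param thresholds TPM thresholds, default `c(0.5, 1, 2, 5)`.
#' @return Long `data.frame`, one row per threshold per stage.
#' @export
class_proportion_sweep <- function(sm, classes, thresholds = c(0.5, 1, 2, 5)) {
  do.call(rbind, lapply(thresholds, function(th) class_proportions(sm, classes, th)))
}

as_class_vector <- function(classes, ids) {
  if (is.data.frame(classes)) {
    classes <- stats::setNames(classes$class, classes$transcript_id)
  }
  out <- classes[ids]
  if (any(is.na(out))) stop("class label missing for some transcripts")
  unname(out)
}

#' Stages in which each transcript is expressed
#'
#' @param sm Stage-mean matrix.
#' @param threshold Expression call threshold (strict `>`), default 1 TPM.
#' @return Logical matrix, transcripts x stages.
#' @export
expressed_stages <- function(sm, threshold = 1) {
  stopifnot(threshold >= 0)
  sm > threshold
}

#' Number of stages each transcript is expressed in
#'
#' @inheritParams expressed_stages
#' @return Named integer vector.
#' @export
n_expressed_stages <- function(sm, threshold = 1) {
  rowSums(expressed_stages(sm, threshold))
}

#' Max-normalize stage profiles
#'
#' Each transcript's stage values are divided by its maximum across stages, so
#' the peak stage is 1. All-zero rows stay all-zero. The operation is
#' idempotent.
#'
#' @param sm Stage-mean matrix.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
max_normalize <- function(sm) {
  mx <- apply(sm, 1L, max)
  sweep(sm, 1L, ifelse(mx > 0, mx, 1), "/")
}

#' Deterministic hierarchical row ordering for heatmaps
#'
#' Clusters transcript profiles with centered Pearson correlation distance and
#' average linkage (the conventions of the classic Cluster 3.0 tool), or plain
#' Euclidean distance. Rows constant across stages have undefined correlation
#' distance; when any are present the function falls back to Euclidean
#' distance with a warning. Leaf order is deterministic for a fixed input
#' order; ties are broken by input order (hclust convention).
#'
#' @param m Numeric matrix with at least 2 rows (typically max-normalized).
#' @param metric `"pearson"` (centered correlation distance, default) or
#'   `"euclidean"`.
#' @param linkage Agglomeration method for [stats::hclust()], default
#'   `"average"`.
#' @return List with `order` (integer leaf order), `labels` (row names in leaf
#'   order) and `hclust` (the dendrogram, serializable via
#'   [stats::as.dendrogram()]).
#' @export
hierarchical_order <- function(m, metric = c("pearson", "euclidean"),
                               linkage = "average") {
  metric <- match.arg(metric)
  if (nrow(m) < 2L) stop("need at least 2 rows to cluster")
  if (metric == "pearson") {
    constant <- apply(m, 1L, function(r) stats::sd(r) == 0 || !is.finite(stats::sd(r)))
    if (any(constant)) {
      warning("constant rows under correlation distance; falling back to Euclidean")
      metric <- "euclidean"
    }
  }
  d <- if (metric == "pearson") {
    stats::as.dist(1 - stats::cor(t(m)))
  } else {
    stats::dist(m)
  }
  hc <- stats::hclust(d, method = linkage)
  list(order = hc$order, labels = rownames(m)[hc$order], hclust = hc)
}

#' Write stage profiles (means, normalized values, expression calls) as TSV
#'
#' @param sm Stage-mean matrix.
#' @param path Output path.
#' @param threshold Expression call threshold for the `n_stages_expressed`
#'   column.
#' @return `path`, invisibly.
#' @export
write_stage_profiles <- function(sm, path, threshold = 1) {
  norm <- max_normalize(sm)
  dt <- data.table::data.table(transcript_id = rownames(sm))
  for (st in colnames(sm)) dt[[paste0("tpm_", st)]] <- sm[, st]
  for (st in colnames(sm)) dt[[paste0("norm_", st)]] <- norm[, st]
  dt$n_stages_expressed <- n_expressed_stages(sm, threshold)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
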