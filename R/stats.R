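#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the sup-norm difference of the two empirical CDFs. The p-value is
#' exact when `n1 * n2 <= 10^4` (and ties permit), asymptotic otherwise.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return One-row `data.frame`: `test`, `statistic`, `p_value`, `n1`, `n2`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  exact <- length(x) * length(y) <= 1e4
  res <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  data.frame(test = "ks", statistic = unname(res$statistic),
             p_value = res$p.value, n1 = length(x), n2 = length(y),
             stringsAsFactors = FALSE)
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided, with tie correction under the normal approximation; exact when
#' both samples are small (`n1 * n2 <= 10^4`) and tie-free. When every value
#' in both samples is identical the test is degenerate and `p = 1`.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return One-row `data.frame`: `test`, `statistic` (U for sample `x`),
#'   `p_value`, `n1`, `n2`.
#' @export
ranksum <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  if (length(unique(c(x, y))) == 1L) {
    return(data.frame(test = "wilcoxon", statistic = length(x) * length(y) / 2,
                      p_value = 1, n1 = length(x), n2 = length(y),
                      stringsAsFactors = FALSE))
  }
  exact <- length(x) * length(y) <= 1e4 && !anyDuplicated(c(x, y))
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
  data.frame(test = "wilcoxon", statistic = unname(res$statistic),
             p_value = res$p.value, n1 = length(x), n2 = length(y),
             stringsAsFactors = FALSE)
}

#' KS scan of novelty-score distributions across stages
#'
#' Runs the two-sample KS test on every pair of stages (each stage contributing
#' the novelty scores of the novel transcripts expressed in it) plus a pooled
#' embryonic-versus-postnatal comparison, reporting group medians alongside
#' each p-value. Stage pairs where either side has fewer than 2 values are
#' skipped with a message.
#'
#' @param novelty_by_stage Named list of numeric novelty-score vectors, one
#'   per stage.
#' @param embryonic,postnatal Stage labels for the pooled comparison. P0 is
#'   grouped with the postnatal stages by default.
#' @return `data.frame`: `group1`, `group2`, `n1`, `n2`, `statistic`, `p_value`,
#'   `median1`, `median2`. The pooled comparison is the row with
#'   `group1 == "embryonic"`.
#' @export
stage_pair_novelty_scan <- function(novelty_by_stage,
                                    embryonic = c("E15", "E18"),
                                    postnatal = c("P0", "P3", "P6", "P9")) {
  stages <- names(novelty_by_stage)
  rows <- list()
  if (length(stages) >= 2L) {
    for (i in seq_len(length(stages) - 1L)) {
      for (j in seq(i + 1L, length(stages))) {
        a <- novelty_by_stage[[i]]
        b <- novelty_by_stage[[j]]
        if (length(a) < 2L || length(b) < 2L) {
          message("skipping pair ", stages[i], " vs ", stages[j],
                  ": fewer than 2 values")
          next
        }
        ks <- ks_two_sample(a, b)
        rows[[length(rows) + 1L]] <- data.frame(
          group1 = stages[i], group2 = stages[j],
          n1 = ks$n1, n2 = ks$n2, statistic = ks$statistic,
          p_value = ks$p_value,
          median1 = stats::median(a), median2 = stats::median(b),
          stringsAsFactors = FALSE)
      }
    }
  }
  e <- unlist(novelty_by_stage[intersect(embryonic, stages)], use.names = FALSE)
  p <- unlist(novelty_by_stage[intersect(postnatal, stages)], use.names = FALSE)
  if (length(e) >= 2L && length(p) >= 2L) {
    ks <- ks_two_sample(e, p)
    rows[[length(rows) + 1L]] <- data.frame(
      group1 = "embryonic", group2 = "postnatal",
      n1 = ks$n1, n2 = ks$n2, statistic = ks$statistic, p_value = ks$p_value,
      median1 = stats::median(e), median2 = stats::median(p),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(group1 = character(), group2 = character(), n1 = integer(),
               n2 = integer(), statistic = double(), p_value = double(),
               median1 = double(), median2 = double(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
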