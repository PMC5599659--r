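ref_for_novelty <- function() {
  ref <- rbind(ex_tbl("r1", "chr1", "+", 0, 100),
               ex_tbl("r2", "chr1", "+", 50, 250))
  ref$source <- "reference"
  build_annotation_set(ref)
}

test_that("exonic overlap counts covered bases without double counting", {
  anno <- ref_for_novelty()
  expect_equal(exonic_overlap(ex_tbl("t", "chr1", "+", 0, 100), anno), 100L)
  # two exons against the union [0,250): [0,100)+[200,300) -> 100+50
  expect_equal(exonic_overlap(ex_tbl("t", "chr1", "+", 0, 100, 200, 300), anno), 150L)
  # absent chromosome is overlap 0, not an error
  expect_equal(exonic_overlap(ex_tbl("t", "chrZ", "+", 0, 100), anno), 0L)
  # empty annotation
  empty <- build_annotation_set(ex_tbl("x", "c", "+", 0, 1)[0, ])
  expect_equal(exonic_overlap(ex_tbl("t", "chr1", "+", 0, 100), empty), 0L)
})

test_that("novelty score follows (1 - overlap/length) * 100 exactly", {
  anno <- ref_for_novelty()
  expect_equal(novelty_score(ex_tbl("t", "chrZ", "+", 0, 100), anno), 100)
  expect_equal(novelty_score(ex_tbl("t", "chr1", "+", 0, 100), anno), 0)
  # 30 of 100 exonic bases overlapping -> NS 70
  expect_equal(novelty_score(ex_tbl("t", "chr1", "+", 220, 250, 400, 470), anno), 70)
})

test_that("classification partitions transcripts with the CNT boundary at 70", {
  anno <- ref_for_novelty()
  # exact chain match -> known
  expect_equal(classify_transcript(ex_tbl("t", "chr1", "+", 0, 100), anno), "known")
  # NS = 0 without an exact chain match (contained fragment) -> PNT, not known
  expect_equal(classify_transcript(ex_tbl("t", "chr1", "+", 10, 90), anno), "PNT")
  # NS = 70 exactly -> CNT (boundary inclusive to CNT)
  expect_equal(classify_transcript(ex_tbl("t", "chr1", "+", 220, 250, 400, 470), anno), "CNT")
  # NS just below 70 -> PNT
  nt <- novelty_scores(ex_tbl("t", "chr1", "+", 219, 250, 400, 470), anno)
  expect_lt(nt$novelty_score, 70)
  expect_equal(nt$class, "PNT")
  # every transcript gets exactly one label
  many <- rbind(ex_tbl("a", "chr1", "+", 0, 100),
                ex_tbl("b", "chr1", "+", 10, 90),
                ex_tbl("c", "chrZ", "+", 0, 500))
  nt <- novelty_scores(many, anno)
  expect_true(all(nt$class %in% c("known", "PNT", "CNT")))
  expect_equal(nrow(nt), 3L)
})

test_that("chain matching respects strand compatibility", {
  ref <- ex_tbl("r1", "chr1", "+", 0, 100)
  ref$source <- "reference"
  anno <- build_annotation_set(ref)
  expect_equal(classify_transcript(ex_tbl("t", "chr1", "-", 0, 100), anno), "PNT")
  expect_equal(classify_transcript(ex_tbl("t", "chr1", "*", 0, 100), anno), "known")
})

test_that("overlap agrees with the per-base membership oracle on random instances", {
  withr::with_seed(42, {
    for (rep in 1:8) {
      n_ref <- sample(2:8, 1)
      s <- sample(0:8000, n_ref)
      w <- sample(20:600, n_ref, replace = TRUE)
      ref <- data.frame(transcript_id = paste0("r", seq_len(n_ref)),
                        gene_id = "g", chrom = "chr1", strand = "+",
                        start = s, end = s + w, source = "reference",
                        stringsAsFactors = FALSE)
      anno <- build_annotation_set(ref)
      ts <- sort(sample(0:9000, 3))
      tx <- ex_tbl("t", "chr1", "+",
                   ts[1], ts[1] + 200, ts[1] + 500, ts[1] + 700)
      expect_equal(exonic_overlap(tx, anno), oracle_overlap_bases(tx, ref))
      ns <- novelty_scores(tx, anno)
      expect_equal(ns$novelty_score,
                   (1 - oracle_overlap_bases(tx, ref) / ns$exonic_length) * 100)
    }
  })
})

test_that("NS is monotone non-increasing in overlap at fixed length", {
  ref <- ex_tbl("r", "chr1", "+", 0, 1000)
  ref$source <- "reference"
  anno <- build_annotation_set(ref)
  # shift a 100-base exon pair to increase annotated overlap stepwise
  ns <- vapply(seq(0, 100, by = 20), function(ov) {
    # ov bases inside the annotation, 100 - ov outside
    exx <- if (ov == 0) ex_tbl("t", "chr1", "+", 2000, 2100)
    else if (ov == 100) ex_tbl("t", "chr1", "+", 0, 100)
    else ex_tbl("t", "chr1", "+", 0, ov, 2000, 2100 - ov)
    novelty_score(exx, anno)
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("strand-aware and span modes behave as documented", {
  ref <- ex_tbl("r1", "chr1", "+", 0, 100)
  ref$source <- "reference"
  anno <- build_annotation_set(ref)
  tx_minus <- ex_tbl("t", "chr1", "-", 0, 100)
  expect_equal(exonic_overlap(tx_minus, anno, strand_mode = "agnostic"), 100L)
  expect_equal(exonic_overlap(tx_minus, anno, strand_mode = "same"), 0L)
  # unknown strand falls back to agnostic under same-strand mode
  tx_unk <- ex_tbl("t", "chr1", "*", 0, 100)
  expect_equal(exonic_overlap(tx_unk, anno, strand_mode = "same"), 100L)
  # span mode: gaps between exons count in the denominator
  tx <- ex_tbl("t", "chr1", "+", 0, 100, 900, 1000)
  expect_equal(novelty_score(tx, anno, length_mode = "exonic"), 50)
  expect_equal(novelty_score(tx, anno, length_mode = "span"), 90)
})
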