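cfg_small <- function(seed = 11, ...) {
  sim_config(seed = seed, n_known = 12, n_pnt = 12, n_cnt = 12, ...)
}

test_that("generation is deterministic: same seed, byte-identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_bundle(cfg_small(), d1)
  simulate_bundle(cfg_small(), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the outputs
  d3 <- withr::local_tempdir()
  simulate_bundle(cfg_small(seed = 12), d3)
  expect_false(identical(readLines(file.path(d1, "assembled.gtf")),
                         readLines(file.path(d3, "assembled.gtf"))))
})

test_that("generated annotation and transcripts satisfy the model invariants", {
  anno <- generate_annotation(cfg_small())
  expect_silent(validate_exon_table(anno$exons))
  asm <- generate_assembled(cfg_small(), anno)
  expect_silent(validate_exon_table(asm$exons))
  expect_equal(nrow(asm$truth), 36L)
  expect_true(all(asm$truth$overlap_bases <= asm$truth$exonic_length))
  # n_genes = 0 yields an empty annotation
  empty <- generate_annotation(sim_config(seed = 1), n_genes = 0)
  expect_equal(nrow(empty$exons), 0L)
})

test_that("planted overlaps reproduce the exact novelty scores downstream", {
  cfg <- cfg_small(seed = 23)
  anno <- generate_annotation(cfg)
  asm <- generate_assembled(cfg, anno)
  nt <- novelty_scores(asm$exons, anno$annotation)
  tr <- asm$truth[match(nt$transcript_id, asm$truth$transcript_id), ]
  expect_equal(nt$overlap_bases, tr$overlap_bases)
  expect_equal(nt$novelty_score, tr$ns_true)
  expect_equal(nt$class, tr$class)            # 100% planted-class recovery
  expect_true(all(nt$novelty_score[tr$class == "known"] == 0))
  expect_true(all(nt$novelty_score[tr$class == "CNT"] >= 70))
  expect_true(all(nt$novelty_score[tr$class == "PNT"] < 70 &
                    nt$novelty_score[tr$class == "PNT"] > 0))
})

test_that("a planted 30% overlap fraction lands exactly on NS = 70", {
  # generator-level contract, checked through the same code path it uses:
  # overlap o = 300 of length L = 1000 carved across the annotation boundary
  ref <- ex_tbl("r", "chr1", "+", 0, 500)
  ref$source <- "reference"
  anno <- build_annotation_set(ref)
  tx <- ex_tbl("t", "chr1", "+", 100, 400, 10000, 10700)
  expect_equal(novelty_score(tx, anno), 70)
  expect_equal(classify_transcript(tx, anno), "CNT")
})

test_that("degenerate conservation config gives constant scores", {
  cfg <- cfg_small()
  cfg$class_conservation_means[] <- 0
  anno <- generate_annotation(cfg)
  asm <- generate_assembled(cfg, anno)
  track <- generate_conservation(cfg, asm$exons, asm$truth)
  expect_true(all(track$intervals$value == 0))
})

test_that("planted expression profiles drive the expected stage calls", {
  cfg <- sim_config(seed = 5, n_known = 20, n_pnt = 20, n_cnt = 60)
  anno <- generate_annotation(cfg)
  asm <- generate_assembled(cfg, anno)
  ex <- generate_expression(cfg, asm$truth)
  sm <- stage_means(ex$eset)
  nst <- n_expressed_stages(sm, 1)
  spec <- ex$profile$transcript_id[ex$profile$profile == "stage_specific"]
  broad <- ex$profile$transcript_id[ex$profile$profile == "broad"]
  expect_gt(length(spec), 0L)
  expect_gt(length(broad), 0L)
  expect_true(all(nst[spec] == 1L))
  expect_true(all(nst[broad] == length(cfg$stages)))
  # planted stage is the called stage
  pl <- ex$profile[ex$profile$profile == "stage_specific", ]
  called <- colnames(sm)[apply(sm[pl$transcript_id, , drop = FALSE], 1, which.max)]
  expect_equal(called, pl$specific_stage)
})

test_that("class expression ordering PNT > known > CNT is recovered by rank-sum", {
  cfg <- sim_config(seed = 19, n_known = 300, n_pnt = 300, n_cnt = 300)
  anno <- generate_annotation(cfg)
  asm <- generate_assembled(cfg, anno)
  ex <- generate_expression(cfg, asm$truth)
  sm <- stage_means(ex$eset)
  cl <- asm$truth$class[match(rownames(sm), asm$truth$transcript_id)]
  tot <- rowMeans(sm)
  expect_lt(ranksum(tot[cl == "PNT"], tot[cl == "known"])$p_value, 1e-3)
  expect_lt(ranksum(tot[cl == "known"], tot[cl == "CNT"])$p_value, 1e-3)
  expect_gt(median(tot[cl == "PNT"]), median(tot[cl == "known"]))
  expect_gt(median(tot[cl == "known"]), median(tot[cl == "CNT"]))
})

test_that("binomial junction counts concentrate on the planted psi", {
  cfg <- sim_config(seed = 2, n_events = 10, read_depth = 100000L)
  spl <- generate_splice_counts(cfg)
  design <- data.frame(sample = unique(spl$counts$sample),
                       stage = sub("_[0-9]+$", "", unique(spl$counts$sample)),
                       replicate = 1)
  est <- stage_psi(spl$counts, design)$stage_psi
  truth <- spl$psi_truth[rownames(est), colnames(est)]
  expect_lt(max(abs(est - truth)), 0.01)
  # true psi = 1 -> zero skip reads, always
  cfg2 <- sim_config(seed = 2, n_events = 4,
                     psi_truth = matrix(1, 4, 6,
                       dimnames = list(NULL, sim_config()$stages)))
  spl2 <- generate_splice_counts(cfg2)
  expect_true(all(spl2$counts$skip == 0))
})

test_that("planted ORFs are reported at the planted strand/frame/offset", {
  cfg <- sim_config(seed = 13, n_known = 5, n_pnt = 5, n_cnt = 30)
  anno <- generate_annotation(cfg)
  asm <- generate_assembled(cfg, anno)
  sq <- generate_sequences(cfg, asm$truth)
  expect_gt(nrow(sq$orf_truth), 0L)
  hits <- orf_table(sq$seqs)
  found <- merge(sq$orf_truth, hits,
                 by = c("transcript_id", "strand", "frame",
                        "start_offset", "length_codons"))
  expect_equal(nrow(found), nrow(sq$orf_truth))
  # stop-salted background never carries an ORF above the length floor
  plain <- setdiff(names(sq$seqs), sq$orf_truth$transcript_id)
  expect_length(intersect(hits$transcript_id, plain), 0L)
})

test_that("the planted novelty shift is detectable by KS with high power", {
  rej <- vapply(1:60, function(i) {
    g <- generate_novelty_shift(500, shift = 2, seed = 1000 + i)
    ks_two_sample(g$embryonic, g$postnatal)$p_value <= 0.005
  }, logical(1))
  expect_gte(mean(rej), 0.9)
  # medians sit near the configured scale, shifted group above baseline
  g <- generate_novelty_shift(2000, shift = 2, seed = 1)
  expect_gt(median(g$embryonic), median(g$postnatal))
})
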