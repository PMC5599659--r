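test_that("psi follows the length-normalized density formula", {
  expect_equal(psi(10, 10, 1, 1), 0.5)                 # symmetry
  expect_equal(psi(7, 0, 2, 1), 1)                     # no skip reads
  expect_equal(psi(2, 8, 2, 1), 1 / 9)                 # worked example
  expect_true(is.na(psi(0, 0, 2, 1)))                  # undefined
  # equal effective lengths reduce to I / (I + S)
  expect_equal(psi(3, 9, 5, 5), 3 / 12)
  # invariant under joint scaling of the counts
  expect_equal(psi(20, 80, 2, 1), psi(2000, 8000, 2, 1))
})

test_that("stage psi averages replicates and reports NA stages", {
  counts <- data.frame(
    event_id = "e1",
    sample = c("E15_1", "E15_2", "P9_1", "P9_2"),
    inclusion = c(40, 60, 0, 0),
    skip = c(60, 40, 0, 0),
    stringsAsFactors = FALSE)
  design <- data.frame(sample = counts$sample,
                       stage = c("E15", "E15", "P9", "P9"),
                       replicate = c(1, 2, 1, 2))
  sp <- stage_psi(counts, design)
  expect_equal(unname(sp$stage_psi["e1", "E15"]), 0.5)  # mean of 0.4 and 0.6
  expect_true(is.na(sp$stage_psi["e1", "P9"]))          # no defined replicate
})

test_that("delta psi and fold change reproduce the exemplar stage pair", {
  m <- matrix(c(0.0535, 0.245), 1, dimnames = list("srsf2_se", c("E15", "P9")))
  d <- delta_psi(m, "E15", "P9")
  expect_equal(d$delta_psi, 0.245 - 0.0535)
  expect_gte(d$fold_change, 4.5)
  expect_equal(d$fold_change, 0.245 / 0.0535)
  # identical stage psi -> delta 0; psi_a = 0 -> fold undefined
  m2 <- matrix(c(0.3, 0.3, 0, 0.2), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  d2 <- delta_psi(m2, "s1", "s2")
  expect_equal(d2$delta_psi, c(0, 0.2))
  expect_true(is.na(d2$fold_change[2]))
})

test_that("the exact-test screen flags separated counts and spares identical ones", {
  design <- data.frame(sample = c("A_1", "B_1"), stage = c("A", "B"),
                       replicate = 1)
  mk <- function(ia, sa, ib, sb, ev = "e") {
    data.frame(event_id = ev, sample = c("A_1", "B_1"),
               inclusion = c(ia, ib), skip = c(sa, sb),
               stringsAsFactors = FALSE)
  }
  # identical pooled counts: never flagged
  same <- screen_events(mk(50, 50, 50, 50), design, "A", "B", alpha_fdr = 0.5)
  expect_false(same$flagged)
  expect_equal(same$p_value, 1)
  # (90,10) vs (10,90): flagged at q < 0.01, p equals the exact-test oracle
  sep <- screen_events(mk(90, 10, 10, 90), design, "A", "B")
  expect_true(sep$flagged)
  expect_equal(sep$p_value,
               fisher.test(matrix(c(90, 10, 10, 90), 2))$p.value)
  # degenerate zero margin -> q = 1
  degen <- screen_events(mk(0, 0, 0, 0), design, "A", "B")
  expect_equal(degen$q_value, 1)
})

test_that("BED export scales psi to 0-1000 and skips undefined cells", {
  tabs <- read_se_psi_table()
  expect_message(bed <- events_to_bed(tabs$events, tabs$stage_psi, "E15"),
                 "skipped")
  defined <- !is.na(tabs$stage_psi[, "E15"])
  expect_equal(nrow(bed), sum(defined))
  expect_true(all(bed$score >= 0 & bed$score <= 1000))
  expect_equal(bed$score,
               as.integer(round(tabs$stage_psi[defined, "E15"] * 1000)))
  # psi 1.0 -> score 1000 (Pax6-like fully included exon at E18)
  bed18 <- suppressMessages(events_to_bed(tabs$events, tabs$stage_psi, "E18"))
  expect_true(1000 %in% bed18$score)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(bed, f)
  expect_equal(nrow(read_bed(f)), nrow(bed))
})

test_that("stage psi matrix writes and reads back with NA cells", {
  tabs <- read_se_psi_table()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_psi_matrix(tabs$stage_psi, f)
  back <- as.data.frame(data.table::fread(f, na.strings = "NA"))
  m <- as.matrix(back[, -1])
  rownames(m) <- back$event_id
  expect_equal(m, tabs$stage_psi)
})
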