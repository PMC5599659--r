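toy_eset <- function(with_e155 = FALSE) {
  stages <- c("E15", "E18", "P0", "P3", "P6", "P9")
  if (with_e155) stages <- c(stages, "E15.5")
  samples <- as.vector(vapply(stages, function(s) paste(s, 1:2, sep = "_"),
                              character(2)))
  m <- matrix(0, 3, length(samples), dimnames = list(c("t1", "t2", "t3"), samples))
  m["t1", c("E18_1", "E18_2")] <- c(2, 4)        # replicate mean 3
  m["t1", c("P6_1", "P6_2")] <- 6
  m["t2", ] <- 10                                 # everywhere
  design <- data.frame(sample = samples, stage = sub("_[0-9]$", "", samples),
                       replicate = as.integer(sub(".*_", "", samples)),
                       stringsAsFactors = FALSE)
  expression_set(m, design)
}

test_that("stage means average replicates and honor the E15.5 exclusion", {
  eset <- toy_eset(with_e155 = TRUE)
  sm <- stage_means(eset)
  expect_false("E15.5" %in% colnames(sm))
  expect_equal(unname(sm["t1", "E18"]), 3)
  expect_equal(unname(sm["t1", "P6"]), 6)
  sm_all <- stage_means(eset, include_excluded = TRUE)
  expect_true("E15.5" %in% colnames(sm_all))
  # single replicate is the identity; 3 replicates 1/2/6 -> 3
  m <- matrix(c(5, 1, 2, 6), 1, dimnames = list("t", c("a", "b", "c", "d")))
  d <- data.frame(sample = c("a", "b", "c", "d"),
                  stage = c("S1", "S2", "S2", "S2"), replicate = c(1, 1, 2, 3))
  sm2 <- stage_means(expression_set(m, d, excluded_stages = character(0)))
  expect_equal(unname(sm2["t", ]), c(5, 3))
})

test_that("class proportions split expressed transcripts and sum to 100%", {
  sm <- matrix(c(2, 2, 2, 2, 0.5, 0.2), 6, 1,
               dimnames = list(paste0("t", 1:6), "E15"))
  classes <- c(t1 = "known", t2 = "known", t3 = "known", t4 = "PNT",
               t5 = "CNT", t6 = "CNT")
  cp <- class_proportions(sm, classes, threshold = 1)
  expect_equal(cp$pct_known, 75)
  expect_equal(cp$pct_novel, 25)
  expect_equal(cp$pct_known + cp$pct_novel, 100)
  # nothing expressed -> undefined marker
  cp0 <- class_proportions(sm, classes, threshold = 100)
  expect_true(is.na(cp0$pct_known))
  # sweep emits one row per threshold per stage
  sw <- class_proportion_sweep(sm, classes, thresholds = c(0.5, 1, 2, 5))
  expect_equal(nrow(sw), 4L)
  defined <- !is.na(sw$pct_known)
  expect_true(all(abs(sw$pct_known[defined] + sw$pct_novel[defined] - 100) < 1e-9))
})

test_that("expressed-stage sets respond to the threshold monotonically", {
  eset <- toy_eset()
  sm <- stage_means(eset)
  es <- expressed_stages(sm, 1)
  expect_equal(sum(es["t1", ]), 2)
  expect_equal(colnames(sm)[es["t1", ]], c("E18", "P6"))
  expect_equal(sum(es["t2", ]), 6)   # all stages
  expect_equal(sum(es["t3", ]), 0)
  # raising the threshold never adds a stage
  for (th in c(0, 0.5, 2, 5, 20)) {
    expect_true(all(expressed_stages(sm, th + 1) <= expressed_stages(sm, th)))
  }
})

test_that("max-normalization peaks at 1, keeps zeros, and is idempotent", {
  sm <- matrix(c(1, 2, 4, 0, 0, 0, 5, 5, 5), 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  nm <- max_normalize(sm)
  expect_equal(unname(nm["a", ]), c(0.25, 0.5, 1))
  expect_equal(unname(nm["b", ]), c(0, 0, 0))
  expect_equal(unname(nm["c", ]), c(1, 1, 1))
  expect_equal(max_normalize(nm), nm)
})

test_that("hierarchical ordering is deterministic and matches a brute-force oracle", {
  withr::with_seed(9, {
    m <- matrix(rnorm(15), 5, 3, dimnames = list(paste0("t", 1:5), NULL))
  })
  res <- hierarchical_order(m, metric = "euclidean")
  d <- as.matrix(dist(m))
  oracle <- oracle_average_linkage(d)
  expect_equal(sort(res$hclust$height), sort(oracle$heights), tolerance = 1e-10)
  # identical pair merges first, at distance 0
  m2 <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), far = c(9, 9, 9))
  res2 <- hierarchical_order(m2, metric = "euclidean")
  expect_equal(res2$hclust$height[1], 0)
  expect_equal(sort(res2$hclust$merge[1, ]), c(-2, -1))
  # determinism for a fixed input
  expect_identical(res$order, hierarchical_order(m, metric = "euclidean")$order)
})

test_that("constant rows under correlation distance fall back with a warning", {
  m <- rbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(3, 2, 1))
  expect_warning(res <- hierarchical_order(m, metric = "pearson"), "Euclidean")
  expect_length(res$order, 3L)
})
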