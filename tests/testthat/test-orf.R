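test_that("hand-checkable ORFs are found with correct geometry", {
  # ATG AAA TAA: one forward frame-0 hit of 3 codons... with min_codons 1
  h <- find_orfs("ATGAAATAA", min_codons = 1)
  fwd <- h[h$strand == "+", ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$frame, 0L)
  expect_equal(fwd$start_codon, "ATG")
  expect_equal(fwd$length_codons, 2L)            # ATG AAA, stop excluded
  expect_equal(fwd$end_offset - fwd$start_offset, 6L)
  # reverse-strand detection: revcomp("TTACATGGG...") carries the ORF
  s <- revcomp("ATGAAAAAATAA")
  h2 <- find_orfs(s, min_codons = 1)
  rev <- h2[h2$strand == "-", ]
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$start_codon, "ATG")
  expect_equal(rev$length_codons, 3L)
})

test_that("the start-codon set is honored", {
  s <- "CTGAAATAA"
  expect_equal(nrow(find_orfs(s, start_codons = "ATG", min_codons = 1)), 0L)
  h <- find_orfs(s, start_codons = c("ATG", "CTG", "GTG", "TTG"), min_codons = 1)
  expect_equal(h$start_codon[h$strand == "+"], "CTG")
  expect_equal(h$length_codons[h$strand == "+"], 2L)
})

test_that("codons containing N never open or close an ORF", {
  # ANG is not a start; the only hit uses the later ATG
  h <- find_orfs("ANGATGAAATAA", min_codons = 1)
  expect_true(all(h$start_codon != "ANG"))
  fwd <- h[h$strand == "+" & h$frame == 0L, ]
  expect_equal(fwd$start_offset, 3L)
  # TNA is not a stop: the ORF reads through it
  h2 <- find_orfs("ATGTNAAAATAA", min_codons = 1)
  fwd2 <- h2[h2$strand == "+" & h2$frame == 0L, ]
  expect_equal(fwd2$length_codons, 3L)
})

test_that("require_stop and all_starts modes behave as documented", {
  s <- "ATGAAAAAAAAA"       # no stop at all
  expect_equal(nrow(find_orfs(s, min_codons = 1)), 0L)
  open <- find_orfs(s, min_codons = 1, require_stop = FALSE)
  expect_true(any(open$strand == "+" & open$length_codons == 4L))
  # nested starts: first-start policy reports one, all_starts both
  s2 <- "ATGAAAATGAAATAA"
  first <- find_orfs(s2, min_codons = 1)
  expect_equal(sum(first$strand == "+" & first$frame == 0L), 1L)
  all_h <- find_orfs(s2, min_codons = 1, all_starts = TRUE)
  expect_equal(sum(all_h$strand == "+" & all_h$frame == 0L), 2L)
})

test_that("longest_orf applies the deterministic tie-break", {
  hits <- data.frame(
    transcript_id = "t", strand = c("-", "+", "+"), frame = c(1L, 0L, 2L),
    start_offset = c(0L, 30L, 6L), end_offset = c(120L, 150L, 126L),
    start_codon = "ATG", length_codons = c(40L, 40L, 10L),
    stringsAsFactors = FALSE)
  top <- longest_orf(hits)
  expect_equal(top$strand, "+")    # + beats - on equal length
  expect_equal(top$frame, 0L)
  expect_null(longest_orf(hits[0, ]))
})

test_that("scanner agrees with the brute-force six-frame oracle on random sequences", {
  withr::with_seed(1234, {
    for (i in 1:20) {
      s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
      got <- find_orfs(s, min_codons = 5)
      want <- oracle_orfs(s, min_codons = 5)
      cols <- c("strand", "frame", "start_offset", "end_offset",
                "start_codon", "length_codons")
      got <- got[do.call(order, got[cols]), cols]
      want <- want[do.call(order, want[cols]), cols]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want)
    }
  })
})

test_that("strand symmetry: scanning the reverse complement swaps strands", {
  withr::with_seed(77, {
    s <- paste(sample(c("A", "C", "G", "T"), 240, replace = TRUE), collapse = "")
  })
  a <- find_orfs(s, min_codons = 4)
  b <- find_orfs(revcomp(s), min_codons = 4)
  swap <- function(df) {
    df$strand <- ifelse(df$strand == "+", "-", "+")
    df[do.call(order, df[c("strand", "frame", "start_offset")]), ]
  }
  a2 <- swap(a)
  b2 <- b[do.call(order, b[c("strand", "frame", "start_offset")]), ]
  rownames(a2) <- rownames(b2) <- NULL
  expect_equal(a2[c("strand", "start_offset", "length_codons", "start_codon")],
               b2[c("strand", "start_offset", "length_codons", "start_codon")])
})

test_that("transcripts with ORFs decrease as min_codons rises", {
  withr::with_seed(31, {
    seqs <- vapply(1:15, function(i)
      paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = ""),
      character(1))
  })
  names(seqs) <- paste0("t", 1:15)
  n_with <- vapply(c(5L, 10L, 20L, 40L), function(mc) {
    length(unique(orf_table(seqs, min_codons = mc)$transcript_id))
  }, integer(1))
  expect_true(all(diff(n_with) <= 0))
})
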