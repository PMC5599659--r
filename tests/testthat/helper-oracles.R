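# Independent brute-force oracles and tiny builders used across the suite.

# exon table builder: ex("t1", "chr1", "+", 0, 100, 200, 300) -> 2 exons
ex_tbl <- function(transcript_id, chrom, strand, ..., gene_id = transcript_id,
                   source = "assembled") {
  pos <- c(...)
  stopifnot(length(pos) %% 2 == 0)
  s <- pos[seq(1, length(pos), by = 2)]
  e <- pos[seq(2, length(pos), by = 2)]
  data.frame(transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
             strand = strand, start = as.integer(s), end = as.integer(e),
             source = source, stringsAsFactors = FALSE)
}

# per-base membership oracle for exonic overlap (instances <= ~10 kb)
oracle_overlap_bases <- function(tx_exons, ref_exons) {
  base_key <- function(df) {
    unlist(mapply(function(ch, s, e) paste0(ch, ":", seq.int(s, e - 1L)),
                  df$chrom, df$start, df$end, SIMPLIFY = FALSE),
           use.names = FALSE)
  }
  if (nrow(ref_exons) == 0L) return(0L)
  length(intersect(unique(base_key(tx_exons)), unique(base_key(ref_exons))))
}

# brute-force union size in bases
oracle_union_bases <- function(ref_exons) {
  if (nrow(ref_exons) == 0L) return(0L)
  keys <- unlist(mapply(function(ch, s, e) paste0(ch, ":", seq.int(s, e - 1L)),
                        ref_exons$chrom, ref_exons$start, ref_exons$end,
                        SIMPLIFY = FALSE), use.names = FALSE)
  length(unique(keys))
}

# six-frame ORF oracle: test every position as a candidate start and walk to
# the next in-frame stop; first-start-per-segment = minimal start per
# (strand, frame, stop). Independent of the package scanner.
oracle_orfs <- function(seq, start_codons = c("ATG", "CTG", "GTG", "TTG"),
                        min_codons = 25L, require_stop = TRUE) {
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (str in c("+", "-")) {
    s <- if (str == "+") toupper(seq) else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
    L <- nchar(s)
    for (p in 0:(L - 3)) {
      cod <- substr(s, p + 1, p + 3)
      if (grepl("N", cod, fixed = TRUE) || !(cod %in% start_codons)) next
      q <- p
      ended_at_stop <- FALSE
      while (q + 3 <= L) {
        c2 <- substr(s, q + 1, q + 3)
        if (!grepl("N", c2, fixed = TRUE) && c2 %in% stops && q > p) {
          ended_at_stop <- TRUE
          break
        }
        if (q == p && c2 %in% stops) break  # start codon cannot be a stop here
        q <- q + 3
      }
      end_off <- q
      if (!ended_at_stop && require_stop) next
      if (!ended_at_stop) end_off <- p + 3 * ((L - p) %/% 3)
      len <- (end_off - p) %/% 3
      if (len < min_codons) next
      out[[length(out) + 1L]] <- data.frame(
        strand = str, frame = p %% 3, start_offset = p, end_offset = end_off,
        start_codon = cod, length_codons = len, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(strand = character(), frame = integer(),
                      start_offset = integer(), end_offset = integer(),
                      start_codon = character(), length_codons = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  # first start per stop-delimited segment
  key <- paste(df$strand, df$frame, df$end_offset)
  keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(i) {
    i[which.min(df$start_offset[i])]
  }), use.names = FALSE)
  df <- df[sort(keep), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# O(n^3) average-linkage agglomeration oracle: returns merge heights and the
# partition (as sorted member lists) formed at each merge.
oracle_average_linkage <- function(d_mat) {
  n <- nrow(d_mat)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq(i + 1L, length(clusters))) {
        dd <- mean(d_mat[clusters[[i]], clusters[[j]]])
        if (dd < best_d - 1e-12) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
    heights <- c(heights, best_d)
    partitions[[length(partitions) + 1L]] <- merged
  }
  list(heights = heights, partitions = partitions)
}

# deterministic synthetic stage-mean TPM for the bundled high-confidence CNT
# records: "broad" rows get > 5 TPM in four stages, "specific" rows positive
# TPM in at most two stages. Synthetic stand-in (the printed table carries no
# expression values).
synthetic_highconf_sm <- function(records,
                                  stages = c("E15", "E18", "P0", "P3", "P6", "P9")) {
  sm <- matrix(0, nrow(records), length(stages),
               dimnames = list(records$transcript_id, stages))
  broad <- records$filter_set == "broad"
  sm[broad, 1:4] <- 6
  sm[broad, 5] <- 0.5
  specific <- records$filter_set == "specific"
  sm[specific, 3] <- 2
  sm[specific, 4] <- 0.4
  sm
}
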