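#' Simulation configuration
#'
#' Collects the parameters of the synthetic study: transcript class counts,
#' developmental stages with replicates, class-wise conservation means
#' (defaults 0.67 / 0.76 / 0.13 for known / PNT / CNT, the published class
#' medians), class-wise expression scale with the ordering PNT > known > CNT,
#' splice-event truth and sequencing depth. All generators are deterministic
#' for a fixed `seed`.
#'
#' @param seed Integer master seed.
#' @param n_known,n_pnt,n_cnt Transcript counts per planted class.
#' @param stages Ordered developmental stage labels.
#' @param replicates_per_stage Biological replicates per stage.
#' @param class_conservation_means Named vector, mean per-base conservation
#'   per class, each in `[0, 1]`.
#' @param class_expression_scale Named vector of log-mean TPM per class.
#' @param cnt_partial_fraction Fraction of CNTs planted with partial overlap
#'   (70 <= NS < 100) instead of NS = 100.
#' @param cnt_stage_specific_fraction,cnt_broad_fraction Fractions of CNTs
#'   planted as expressed in exactly one stage / in every stage.
#' @param n_events Number of splice events.
#' @param read_depth Junction reads per event per sample.
#' @param psi_truth Optional events x stages matrix of true psi values in
#'   `[0, 1]`; generated when `NULL`.
#' @param orf_fraction Fraction of CNT sequences carrying a planted ORF.
#' @param orf_codons Planted ORF length in codons (start included).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_known = 50L, n_pnt = 50L, n_cnt = 50L,
                       stages = c("E15", "E18", "P0", "P3", "P6", "P9"),
                       replicates_per_stage = 2L,
                       class_conservation_means = c(known = 0.67, PNT = 0.76, CNT = 0.13),
                       class_expression_scale = c(known = log(15), PNT = log(40), CNT = log(1.2)),
                       cnt_partial_fraction = 0.1,
                       cnt_stage_specific_fraction = 0.10,
                       cnt_broad_fraction = 0.47,
                       n_events = 24L,
                       read_depth = 5000L,
                       psi_truth = NULL,
                       orf_fraction = 0.5,
                       orf_codons = 60L) {
  stopifnot(n_known >= 0, n_pnt >= 0, n_cnt >= 0,
            all(class_conservation_means >= 0 & class_conservation_means <= 1),
            replicates_per_stage >= 1, read_depth >= 1)
  if (!is.null(psi_truth)) stopifnot(all(psi_truth >= 0 & psi_truth <= 1))
  structure(
    list(seed = as.integer(seed), n_known = as.integer(n_known),
         n_pnt = as.integer(n_pnt), n_cnt = as.integer(n_cnt),
         stages = stages, replicates_per_stage = as.integer(replicates_per_stage),
         class_conservation_means = class_conservation_means,
         class_expression_scale = class_expression_scale,
         cnt_partial_fraction = cnt_partial_fraction,
         cnt_stage_specific_fraction = cnt_stage_specific_fraction,
         cnt_broad_fraction = cnt_broad_fraction,
         n_events = as.integer(n_events),
         read_depth = as.integer(read_depth),
         psi_truth = psi_truth,
         orf_fraction = orf_fraction, orf_codons = as.integer(orf_codons)),
    class = "sim_config"
  )
}

# independent sub-seed per generator stage, kept under 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}

#' Generate a toy reference annotation
#'
#' Multi-exon genes with realistic intron gaps are laid out on a toy genome of
#' named chromosomes (`chrS1`, `chrS2`, ...; up to 2 Mb each, more chromosomes
#' added as needed). Genes occupy the first 60% of each chromosome; the
#' remainder is reserved annotation-free space where completely novel
#' transcripts can be planted. Deterministic for a fixed seed.
#'
#' @param config A `sim_config`.
#' @param n_genes Number of genes; by default enough to host the known and
#'   PNT transcripts.
#' @return List with `exons` (reference exon table), `annotation`
#'   (`annotation_set`) and `free_zones` (`data.frame` of annotation-free
#'   intervals per chromosome).
#' @export
generate_annotation <- function(config, n_genes = NULL) {
  if (is.null(n_genes)) {
    n_genes <- max(20L, config$n_known, ceiling(config$n_pnt / 2))
  }
  chrom_len <- 2e6L
  zone_end <- 1.2e6  # genes live in [0, zone_end); rest is free space
  withr::with_seed(derive_seed(config$seed, 1L), {
    rows <- list()
    chrom_i <- 1L
    pos <- 0L
    for (g in seq_len(n_genes)) {
      n_ex <- sample(2:8, 1L)
      ex_len <- sample(100:400, n_ex, replace = TRUE)
      introns <- sample(200:1500, max(n_ex - 1L, 0L), replace = TRUE)
      gene_len <- sum(ex_len) + sum(introns)
      if (pos + gene_len >= zone_end) {
        chrom_i <- chrom_i + 1L
        pos <- 0L
      }
      strand <- sample(c("+", "-"), 1L)
      starts <- pos + cumsum(c(0L, ex_len[-n_ex] + introns))
      rows[[g]] <- data.frame(
        transcript_id = sprintf("REF.%d.1", g),
        gene_id = sprintf("REFG.%d", g),
        chrom = paste0("chrS", chrom_i),
        strand = strand,
        start = as.integer(starts),
        end = as.integer(starts + ex_len),
        source = "reference",
        stringsAsFactors = FALSE
      )
      pos <- pos + gene_len + sample(2000:8000, 1L)
    }
    exons <- if (n_genes > 0L) do.call(rbind, rows) else empty_exon_table("reference")
  })
  chroms <- if (n_genes > 0L) paste0("chrS", seq_len(max(1L, chrom_i))) else "chrS1"
  free_zones <- data.frame(
    chrom = chroms,
    start = as.integer(zone_end + 1e4),
    end = chrom_len,
    stringsAsFactors = FALSE
  )
  list(exons = exons, annotation = build_annotation_set(exons),
       free_zones = free_zones)
}

# sequential allocator over annotation-free zones (env with per-chrom cursor)
make_free_allocator <- function(free_zones) {
  env <- new.env(parent = emptyenv())
  env$zones <- free_zones
  env$cursor <- stats::setNames(free_zones$start, free_zones$chrom)
  env$i <- 1L
  alloc <- function(len, chrom = NULL) {
    if (is.null(chrom)) {
      chrom <- free_zones$chrom[(env$i - 1L) %% nrow(free_zones) + 1L]
      env$i <- env$i + 1L
    }
    cur <- env$cursor[[chrom]]
    zend <- free_zones$end[free_zones$chrom == chrom]
    if (cur + len + 500 > zend) {
      # round-robin to any chromosome with room before giving up
      for (alt in free_zones$chrom) {
        if (env$cursor[[alt]] + len + 500 <= free_zones$end[free_zones$chrom == alt]) {
          chrom <- alt
          cur <- env$cursor[[alt]]
          zend <- free_zones$end[free_zones$chrom == alt]
          break
        }
      }
      if (cur + len + 500 > zend) {
        stop("no annotation-free space left; enlarge the toy genome ",
             "(more chromosomes or fewer transcripts)")
      }
    }
    env$cursor[[chrom]] <- as.integer(cur + len + 500L)
    list(chrom = chrom, start = as.integer(cur))
  }
  alloc
}

#' Generate assembled transcripts with planted novelty classes
#'
#' Plants three classes against the toy annotation with exact base-level
#' control of the overlap, so the true novelty score is known without rounding
#' drift:
#' * known -- copies a reference exon chain exactly (overlap fraction 1,
#'   NS = 0);
#' * PNT -- a two-exon transcript: one exon of `o` bases inside a reference
#'   exon, one exon of `L - o` bases in annotation-free space, with
#'   `o / L > 0.3` so NS < 70;
#' * CNT -- placed entirely in annotation-free space (NS = 100), except a
#'   configurable minority built like PNTs with `o / L <= 0.3` (70 <= NS < 100).
#'
#' @param config A `sim_config`.
#' @param anno Result of [generate_annotation()].
#' @return List with `exons` (assembled exon table) and `truth` (`data.frame`:
#'   `transcript_id`, `class`, `overlap_bases`, `exonic_length`, `ns_true`).
#' @export
generate_assembled <- function(config, anno) {
  ref <- anno$exons
  if ((config$n_known > 0L || config$n_pnt > 0L) && nrow(ref) == 0L) {
    stop("annotation is empty but known/PNT transcripts were requested")
  }
  alloc <- make_free_allocator(anno$free_zones)
  withr::with_seed(derive_seed(config$seed, 2L), {
    rows <- list()
    truth <- list()
    ref_tx <- unique(ref$transcript_id)
    # known: exact chain copies
    if (config$n_known > 0L) {
      picks <- sample(ref_tx, config$n_known, replace = config$n_known > length(ref_tx))
      for (i in seq_len(config$n_known)) {
        src <- ref[ref$transcript_id == picks[i], , drop = FALSE]
        id <- sprintf("ASM.K.%d", i)
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = id, gene_id = src$gene_id[1L], chrom = src$chrom,
          strand = src$strand, start = src$start, end = src$end,
          source = "assembled", stringsAsFactors = FALSE)
        len <- sum(src$end - src$start)
        truth[[length(truth) + 1L]] <- data.frame(
          transcript_id = id, class = "known", overlap_bases = len,
          exonic_length = len, ns_true = 0, stringsAsFactors = FALSE)
      }
    }
    # hosts for partial-overlap constructions: reference exons wide enough
    wide <- ref[ref$end - ref$start >= 150L, , drop = FALSE]
    plant_partial <- function(id, f_lo, f_hi, strict_over_030) {
      host <- wide[sample(nrow(wide), 1L), , drop = FALSE]
      w <- host$end - host$start
      f <- stats::runif(1L, f_lo, f_hi)
      L <- sample(400:1400, 1L)
      o <- if (strict_over_030) ceiling(f * L) else floor(f * L)
      if (o > w) {           # host exon too small for the target overlap
        o <- w
        L <- if (strict_over_030) floor(o / max(f, 0.35)) else ceiling(o / min(f, 0.3))
      }
      o <- as.integer(o); L <- as.integer(L)
      stopifnot(o >= 1L, L > o)
      off <- sample.int(w - o + 1L, 1L) - 1L
      ex1_start <- host$start + off
      novel_len <- L - o
      spot <- alloc(novel_len, chrom = host$chrom)
      strand <- sample(c("+", "-", "*"), 1L)
      rows[[length(rows) + 1L]] <<- data.frame(
        transcript_id = id, gene_id = paste0(id, ".G"),
        chrom = host$chrom, strand = strand,
        start = c(ex1_start, spot$start),
        end = c(ex1_start + o, spot$start + novel_len),
        source = "assembled", stringsAsFactors = FALSE)
      list(overlap = o, length = L)
    }
    for (i in seq_len(config$n_pnt)) {
      id <- sprintf("ASM.P.%d", i)
      pl <- plant_partial(id, 0.35, 0.90, strict_over_030 = TRUE)
      truth[[length(truth) + 1L]] <- data.frame(
        transcript_id = id, class = "PNT", overlap_bases = pl$overlap,
        exonic_length = pl$length,
        ns_true = (1 - pl$overlap / pl$length) * 100, stringsAsFactors = FALSE)
    }
    n_partial_cnt <- round(config$n_cnt * config$cnt_partial_fraction)
    for (i in seq_len(config$n_cnt)) {
      id <- sprintf("ASM.C.%d", i)
      if (i <= n_partial_cnt && nrow(wide) > 0L) {
        pl <- plant_partial(id, 0.05, 0.30, strict_over_030 = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          transcript_id = id, class = "CNT", overlap_bases = pl$overlap,
          exonic_length = pl$length,
          ns_true = (1 - pl$overlap / pl$length) * 100, stringsAsFactors = FALSE)
      } else {
        n_ex <- sample(1:2, 1L)
        ex_len <- sample(150:900, n_ex, replace = TRUE)
        L <- sum(ex_len)
        spot <- alloc(L + 400L * (n_ex - 1L))
        starts <- spot$start + cumsum(c(0L, (ex_len + 400L)[-n_ex]))
        strand <- sample(c("+", "-", "*"), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = id, gene_id = paste0(id, ".G"),
          chrom = spot$chrom, strand = strand,
          start = as.integer(starts), end = as.integer(starts + ex_len),
          source = "assembled", stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          transcript_id = id, class = "CNT", overlap_bases = 0L,
          exonic_length = L, ns_true = 100, stringsAsFactors = FALSE)
      }
    }
    exons <- if (length(rows)) do.call(rbind, rows) else empty_exon_table("assembled")
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(transcript_id = character(), class = character(),
                 overlap_bases = integer(), exonic_length = integer(),
                 ns_true = double(), stringsAsFactors = FALSE)
  })
  rownames(exons) <- rownames(truth) <- NULL
  validate_exon_table(exons)
  list(exons = exons, truth = truth)
}

#' Generate a conservation track with class-dependent levels
#'
#' Per-base scores are drawn from beta distributions (bounded support, like
#' phastCons probabilities): each transcript gets a latent conservation level
#' `mu ~ Beta` centred on its class mean (concentration 30, giving realistic
#' between-transcript spread while keeping the class median within a few
#' hundredths of the mean), and its exonic bases get values `~ Beta(mu, 30)`
#' drawn in runs of 25 bases (conservation tracks are run-length encoded in
#' practice). A degenerate class mean of 0 (or 1) yields constant scores.
#' Transcripts are laid down known first, then PNT, then CNT, with the
#' last-wins rule resolving the rare shared bases.
#'
#' @param config A `sim_config`.
#' @param exons Assembled exon table.
#' @param truth Ground-truth table from [generate_assembled()].
#' @return A `conservation_track` covering the exonic bases.
#' @export
generate_conservation <- function(config, exons, truth) {
  means <- config$class_conservation_means
  run <- 25L
  cls <- truth$class[match(exons$transcript_id, truth$transcript_id)]
  ord <- order(match(cls, c("known", "PNT", "CNT")))
  exons <- exons[ord, , drop = FALSE]
  cls <- cls[ord]
  withr::with_seed(derive_seed(config$seed, 3L), {
    mu_tx <- new.env(parent = emptyenv())
    draw_mu <- function(tid, m) {
      if (!is.null(mu_tx[[tid]])) return(mu_tx[[tid]])
      v <- if (m <= 0) 0 else if (m >= 1) 1 else stats::rbeta(1L, m * 30, (1 - m) * 30)
      mu_tx[[tid]] <- v
      v
    }
    pieces <- vector("list", nrow(exons))
    for (i in seq_len(nrow(exons))) {
      m <- means[[cls[i]]]
      mu <- draw_mu(exons$transcript_id[i], m)
      w <- exons$end[i] - exons$start[i]
      n_runs <- ceiling(w / run)
      vals <- if (mu <= 0) rep(0, n_runs) else if (mu >= 1) rep(1, n_runs) else
        stats::rbeta(n_runs, mu * 30, (1 - mu) * 30)
      starts <- exons$start[i] + (seq_len(n_runs) - 1L) * run
      ends <- pmin(starts + run, exons$end[i])
      pieces[[i]] <- data.frame(chrom = exons$chrom[i], start = starts,
                                end = ends, value = vals,
                                stringsAsFactors = FALSE)
    }
  })
  conservation_track(do.call(rbind, pieces))
}

#' Generate a stage-wise expression matrix with planted profiles
#'
#' Log-normal TPM with class effects ordered PNT > known > CNT in
#' expectation, independent replicate noise, and two planted CNT profile
#' groups: a subset expressed in exactly one stage and a subset expressed in
#' every stage (both guaranteed by construction at the default TPM > 1 call).
#'
#' @param config A `sim_config`.
#' @param truth Ground-truth table.
#' @return List with `eset` (an `expression_set`) and `profile` (`data.frame`:
#'   `transcript_id`, `profile` in `broad` / `stage_specific` / `free`, and
#'   `specific_stage`).
#' @export
generate_expression <- function(config, truth) {
  stages <- config$stages
  reps <- config$replicates_per_stage
  ids <- truth$transcript_id
  n <- length(ids)
  mu <- config$class_expression_scale[truth$class]
  withr::with_seed(derive_seed(config$seed, 4L), {
    profile <- rep("free", n)
    specific_stage <- rep(NA_character_, n)
    is_cnt <- truth$class == "CNT"
    cnt_idx <- which(is_cnt)
    n_spec <- round(length(cnt_idx) * config$cnt_stage_specific_fraction)
    n_broad <- round(length(cnt_idx) * config$cnt_broad_fraction)
    pick <- sample(cnt_idx)
    spec_idx <- utils::head(pick, n_spec)
    broad_idx <- utils::head(setdiff(pick, spec_idx), n_broad)
    profile[spec_idx] <- "stage_specific"
    profile[broad_idx] <- "broad"
    specific_stage[spec_idx] <- sample(stages, length(spec_idx), replace = TRUE)

    base <- exp(stats::rnorm(n, mean = mu, sd = 0.8))
    m_stage <- matrix(0, n, length(stages), dimnames = list(ids, stages))
    for (s in seq_along(stages)) {
      m_stage[, s] <- base * exp(stats::rnorm(n, 0, 0.4))
    }
    # planted CNT profiles: guaranteed calls at the TPM > 1 default threshold
    for (i in spec_idx) {
      v <- m_stage[i, specific_stage[i]]
      m_stage[i, ] <- 0
      m_stage[i, specific_stage[i]] <- max(v, 2.5)
    }
    for (i in broad_idx) {
      m_stage[i, ] <- pmax(m_stage[i, ], 2.5)
    }
    samples <- as.vector(t(outer(stages, seq_len(reps), paste, sep = "_")))
    tpm <- matrix(0, n, length(samples), dimnames = list(ids, samples))
    for (s in seq_along(stages)) {
      for (r in seq_len(reps)) {
        col <- paste(stages[s], r, sep = "_")
        noise <- exp(stats::rnorm(n, 0, 0.2))
        tpm[, col] <- m_stage[, s] * noise
      }
    }
  })
  design <- data.frame(
    sample = colnames(tpm),
    stage = sub("_[0-9]+$", "", colnames(tpm)),
    replicate = as.integer(sub("^.*_", "", colnames(tpm))),
    stringsAsFactors = FALSE
  )
  list(
    eset = expression_set(tpm, design, excluded_stages = "E15.5"),
    profile = data.frame(transcript_id = ids, profile = profile,
                         specific_stage = specific_stage,
                         stringsAsFactors = FALSE)
  )
}

#' Generate splice events and binomial junction counts
#'
#' Inclusion counts are drawn `I ~ Binomial(depth, g(psi))` with
#' `g(psi) = psi * lI / (psi * lI + (1 - psi) * lS)` -- the length-weighted
#' inclusion probability consistent with the PSI estimator -- and
#' `S = depth - I`. Effective lengths follow the junction-count convention:
#' `lI = 2, lS = 1` for SE/A5SS/A3SS, `lI = lS = 2` for MXE, and RI uses an
#' intron-body ratio (`lI = 2 + round(intron_length / 150)`, `lS = 1`).
#' When `config$psi_truth` is `NULL` a truth matrix is generated with
#' per-event, per-stage psi values, including one exemplar skipped exon whose
#' psi rises from 0.0535 (first stage) to 0.245 (last stage).
#'
#' @param config A `sim_config`.
#' @return List with `events`, `counts` (per sample) and `psi_truth` (matrix
#'   events x stages).
#' @export
generate_splice_counts <- function(config) {
  stages <- config$stages
  reps <- config$replicates_per_stage
  n_ev <- max(config$n_events, 1L)
  types <- rep(SPLICE_TYPES, length.out = n_ev)
  intron_len <- 300L
  withr::with_seed(derive_seed(config$seed, 5L), {
    pos <- cumsum(rep(5000L, n_ev))
    events <- data.frame(
      event_id = sprintf("EV.%s.%d", types, seq_len(n_ev)),
      type = types,
      gene = sprintf("GENE.%d", seq_len(n_ev)),
      chrom = "chrS1",
      start = pos,
      end = pos + ifelse(types == "RI", intron_len, 120L),
      strand = rep(c("+", "-"), length.out = n_ev),
      stringsAsFactors = FALSE
    )
    events$event_id[1L] <- "EV.SE.exemplar"
    events$type[1L] <- "SE"
    psi_truth <- config$psi_truth
    if (is.null(psi_truth)) {
      psi_truth <- matrix(stats::runif(n_ev * length(stages), 0.05, 0.95),
                          n_ev, length(stages),
                          dimnames = list(events$event_id, stages))
      # exemplar skipped exon: inclusion rising ~4.6-fold across the series
      psi_truth[1L, ] <- seq(0.0535, 0.245, length.out = length(stages))
    }
    len_i <- ifelse(events$type == "MXE", 2L,
                    ifelse(events$type == "RI", 2L + round(intron_len / 150), 2L))
    len_s <- ifelse(events$type == "MXE", 2L, 1L)
    rows <- list()
    for (s in seq_along(stages)) {
      for (r in seq_len(reps)) {
        smp <- paste(stages[s], r, sep = "_")
        p_true <- psi_truth[, stages[s]]
        g <- p_true * len_i / (p_true * len_i + (1 - p_true) * len_s)
        inc <- stats::rbinom(n_ev, config$read_depth, g)
        rows[[length(rows) + 1L]] <- data.frame(
          event_id = events$event_id, sample = smp,
          inclusion = inc, skip = config$read_depth - inc,
          len_inclusion = len_i, len_skip = len_s,
          stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(rbind, rows)
  })
  rownames(counts) <- NULL
  list(events = events, counts = counts, psi_truth = psi_truth)
}

# 24-base cassette holding stop codons in all six frames and no G at all
# (so it can never contain a start codon); it is its own reverse complement.
STOP_CASSETTE <- "TAAATAAATAAATTTATTTATTTA"

#' Generate transcript sequences with planted ORFs
#'
#' Background sequence is "stop-codon-salted": random filler interleaved with
#' a 24-base cassette carrying stop codons in all six reading frames every 36
#' bases, which bounds any unplanted ORF to fewer than 25 codons by
#' construction. A configurable subset of CNT transcripts gets a planted ORF
#' (`ATG`, a stop-free random body, terminal `TAA`) at a known strand, frame
#' and offset, flanked by cassettes so the planted start is always the first
#' start of its stop-delimited segment.
#'
#' @param config A `sim_config`.
#' @param truth Ground-truth table.
#' @return List with `seqs` (named character vector, one sequence per
#'   transcript, length = exonic length) and `orf_truth` (`data.frame`:
#'   `transcript_id`, `strand`, `frame`, `start_offset`, `length_codons`).
#' @export
generate_sequences <- function(config, truth) {
  withr::with_seed(derive_seed(config$seed, 6L), {
    non_stop <- setdiff(
      apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                        c("A", "C", "G", "T")), 1L, paste, collapse = ""),
      STOP_CODONS)
    salted <- function(len) {
      out <- character(0)
      total <- 0L
      while (total < len) {
        filler <- paste(sample(c("A", "C", "G", "T"), 36L, replace = TRUE),
                        collapse = "")
        out <- c(out, filler, STOP_CASSETTE)
        total <- total + 60L
      }
      substr(paste(out, collapse = ""), 1L, len)
    }
    cnt_ids <- truth$transcript_id[truth$class == "CNT"]
    n_orf <- round(length(cnt_ids) * config$orf_fraction)
    orf_ids <- if (n_orf > 0L) sample(cnt_ids, n_orf) else character(0)
    seqs <- character(nrow(truth))
    names(seqs) <- truth$transcript_id
    orf_rows <- list()
    for (i in seq_len(nrow(truth))) {
      id <- truth$transcript_id[i]
      L <- max(truth$exonic_length[i], 60L)
      block_len <- 2L * nchar(STOP_CASSETTE) + 3L * (config$orf_codons + 1L)
      if (id %in% orf_ids && L >= block_len + 6L) {
        body <- paste(sample(non_stop, config$orf_codons - 1L, replace = TRUE),
                      collapse = "")
        orf <- paste0("ATG", body, "TAA")
        block <- paste0(STOP_CASSETTE, orf, STOP_CASSETTE)
        strand <- sample(c("+", "-"), 1L)
        s <- salted(L)
        insert_at <- sample.int(L - block_len + 1L, 1L)  # 1-based
        planted <- if (strand == "+") block else revcomp(block)
        substr(s, insert_at, insert_at + block_len - 1L) <- planted
        # offset of the ATG on the scanned strand (0-based)
        orf_off_plus <- insert_at - 1L + nchar(STOP_CASSETTE)
        start_offset <- if (strand == "+") orf_off_plus else
          L - (orf_off_plus + 3L * (config$orf_codons + 1L))
        orf_rows[[length(orf_rows) + 1L]] <- data.frame(
          transcript_id = id, strand = strand,
          frame = start_offset %% 3L,
          start_offset = start_offset,
          length_codons = config$orf_codons,
          stringsAsFactors = FALSE)
        seqs[[id]] <- s
      } else {
        seqs[[id]] <- salted(L)
      }
    }
    orf_truth <- if (length(orf_rows)) do.call(rbind, orf_rows) else
      data.frame(transcript_id = character(), strand = character(),
                 frame = integer(), start_offset = integer(),
                 length_codons = integer(), stringsAsFactors = FALSE)
  })
  list(seqs = seqs, orf_truth = orf_truth)
}

#' Simulate a complete input bundle on disk
#'
#' Runs every generator and writes the standard files: reference and assembled
#' GTFs, a bedGraph conservation track, the expression matrix and design,
#' splice-event and junction-count tables, transcript FASTA, and the
#' ground-truth tables. All files are byte-identical across runs with the
#' same configuration.
#'
#' @param config A `sim_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of all generated in-memory objects plus `paths`.
#' @export
simulate_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  anno <- generate_annotation(config)
  asm <- generate_assembled(config, anno)
  track <- generate_conservation(config, asm$exons, asm$truth)
  expr <- generate_expression(config, asm$truth)
  spl <- generate_splice_counts(config)
  sq <- generate_sequences(config, asm$truth)

  paths <- list(
    annotation = file.path(dir, "annotation.gtf"),
    assembled = file.path(dir, "assembled.gtf"),
    conservation = file.path(dir, "conservation.bedGraph"),
    expression = file.path(dir, "expression.tsv"),
    design = file.path(dir, "design.tsv"),
    events = file.path(dir, "events.tsv"),
    counts = file.path(dir, "junction_counts.tsv"),
    sequences = file.path(dir, "sequences.fa"),
    truth = file.path(dir, "ground_truth.tsv"),
    orf_truth = file.path(dir, "orf_truth.tsv"),
    psi_truth = file.path(dir, "psi_truth.tsv"),
    profile = file.path(dir, "expression_profiles.tsv")
  )
  write_gtf(anno$exons, paths$annotation)
  write_gtf(asm$exons, paths$assembled)
  write_bedgraph(track, paths$conservation)
  write_expression(expr$eset, paths$expression, paths$design)
  data.table::fwrite(spl$events, paths$events, sep = "\t")
  data.table::fwrite(spl$counts, paths$counts, sep = "\t")
  write_fasta(sq$seqs, paths$sequences)
  data.table::fwrite(asm$truth, paths$truth, sep = "\t")
  data.table::fwrite(sq$orf_truth, paths$orf_truth, sep = "\t")
  pt <- data.table::data.table(event_id = rownames(spl$psi_truth))
  for (st in colnames(spl$psi_truth)) pt[[st]] <- spl$psi_truth[, st]
  data.table::fwrite(pt, paths$psi_truth, sep = "\t")
  data.table::fwrite(expr$profile, paths$profile, sep = "\t")

  invisible(list(config = config, annotation = anno, assembled = asm,
                 track = track, expression = expr, splicing = spl,
                 sequences = sq, paths = paths))
}

#' Draw paired novelty-score samples with a planted location shift
#'
#' Emulates comparing the novelty-score distributions of novel transcripts
#' between an embryonic-like and a postnatal-like group: the baseline group is
#' gamma-distributed (shape 3, scale 3; median about 8, matching the scale of
#' stage-wise novelty medians) truncated to `[0, 100]`, and the shifted group
#' adds a constant location shift.
#'
#' @param n Sample size per group.
#' @param shift Location shift in novelty-score units, default 2.
#' @param seed Seed.
#' @return List with numeric vectors `embryonic` (shifted) and `postnatal`.
#' @export
generate_novelty_shift <- function(n = 500L, shift = 2, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    post <- pmin(stats::rgamma(n, shape = 3, scale = 3), 100)
    emb <- pmin(stats::rgamma(n, shape = 3, scale = 3) + shift, 100)
  })
  list(embryonic = emb, postnatal = post)
}
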