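#' Run the full characterization pipeline
#'
#' Orchestrates every stage over files on disk, in order: novelty scoring and
#' classification, conservation aggregation, stage expression profiles,
#' high-confidence filter tables, ORF detection, the PSI matrix, per-stage BED
#' tracks, and a statistics report (KS scan of novelty scores across stages).
#' A manifest records the package version, thresholds, and an MD5 checksum of
#' every input and output. If the conservation track is absent the
#' conservation-dependent stages are skipped with an explicit notice and the
#' rest still run. On a stage failure the half-written output is kept with a
#' `.partial` suffix and the run halts naming the stage.
#'
#' @param annotation,assembled Paths to reference and assembled GTFs.
#' @param out_dir Output directory.
#' @param conservation Optional bedGraph path.
#' @param expression,design Optional expression matrix / design TSV paths.
#' @param events,counts Optional splice-event and junction-count TSV paths.
#' @param sequences Optional transcript FASTA path.
#' @param cnt_cutoff NS class boundary (default 70).
#' @param tpm_threshold Expression call threshold (default 1).
#' @param filter_names Which [builtin_specs()] filters to run.
#' @param novelty_tpm_threshold Expression threshold used when assigning
#'   novelty scores to stages for the KS scan (default 5).
#' @return Invisibly, a named list of output paths (the manifest lists the
#'   same set).
#' @export
run_full <- function(annotation, assembled, out_dir,
                     conservation = NULL, expression = NULL, design = NULL,
                     events = NULL, counts = NULL, sequences = NULL,
                     cnt_cutoff = 70, tpm_threshold = 1,
                     filter_names = c("cnt_broad", "cnt_specific"),
                     novelty_tpm_threshold = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  inputs <- Filter(Negate(is.null),
                   list(annotation = annotation, assembled = assembled,
                        conservation = conservation, expression = expression,
                        design = design, events = events, counts = counts,
                        sequences = sequences))
  stage <- function(name, file, fun) {
    path <- file.path(out_dir, file)
    ok <- tryCatch({ fun(path); TRUE }, error = function(e) {
      if (file.exists(path)) file.rename(path, paste0(path, ".partial"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    outputs[[name]] <<- path
    path
  }

  ref <- read_gtf(annotation, "reference")
  anno <- build_annotation_set(ref)
  asm <- read_gtf(assembled, "assembled")

  nt <- NULL
  stage("novelty", "novelty.tsv", function(p) {
    nt <<- novelty_scores(asm, anno, cnt_cutoff = cnt_cutoff)
    write_novelty(nt, p)
  })

  cons <- NULL
  if (!is.null(conservation) && file.exists(conservation)) {
    stage("conservation", "conservation.tsv", function(p) {
      track <- read_bedgraph(conservation)
      cons <<- transcript_conservation(asm, track)
      write_conservation(cons, p)
    })
  } else {
    message("notice: conservation track missing; ",
            "conservation-dependent stages skipped")
  }

  sm <- NULL
  if (!is.null(expression) && !is.null(design)) {
    stage("stage_profiles", "stage_profiles.tsv", function(p) {
      eset <- read_expression(expression, design)
      sm <<- stage_means(eset)
      write_stage_profiles(sm, p, threshold = tpm_threshold)
    })
  }

  if (!is.null(cons) && !is.null(sm)) {
    specs <- builtin_specs()[filter_names]
    records <- data.frame(
      transcript_id = nt$transcript_id,
      gene_id = nt$gene_id,
      chrom = nt$chrom,
      strand = nt$strand,
      length = nt$exonic_length,
      ps = cons$transcript_score[match(nt$transcript_id, cons$transcript_id)],
      ns = nt$novelty_score,
      class = nt$class,
      stringsAsFactors = FALSE
    )
    for (spec in specs) {
      local({
        s <- spec
        stage(paste0("filter_", s$name), paste0("filter_", s$name, ".tsv"),
              function(p) {
                surv <- apply_filter(records, s, sm = sm)
                data.table::fwrite(surv, p, sep = "\t")
              })
      })
    }
  } else if (!is.null(sm)) {
    message("notice: filter stages skipped (need conservation scores)")
  }

  if (!is.null(sequences) && file.exists(sequences)) {
    stage("orfs", "orfs.tsv", function(p) {
      seqs <- read_fasta(sequences)
      data.table::fwrite(orf_table(seqs), p, sep = "\t")
    })
  }

  psi_m <- NULL
  ev <- NULL
  if (!is.null(events) && !is.null(counts) && !is.null(design)) {
    stage("psi", "psi_matrix.tsv", function(p) {
      ev <<- read_events(events)
      cnts <- read_junction_counts(counts)
      des <- read_design(design)
      psi_m <<- stage_psi(cnts, des)$stage_psi
      write_psi_matrix(psi_m, p)
    })
    dir.create(file.path(out_dir, "tracks"), showWarnings = FALSE)
    for (st in colnames(psi_m)) {
      local({
        stg <- st
        stage(paste0("track_", stg), file.path("tracks", paste0(stg, ".bed")),
              function(p) {
                bed <- suppressMessages(events_to_bed(ev, psi_m, stg))
                write_bed(bed, p)
              })
      })
    }
  }

  if (!is.null(sm)) {
    stage("stats", "stats_report.tsv", function(p) {
      by_stage <- lapply(colnames(sm), function(stg) {
        ids <- rownames(sm)[sm[, stg] > novelty_tpm_threshold]
        nt$novelty_score[nt$transcript_id %in% ids & nt$class != "known"]
      })
      names(by_stage) <- colnames(sm)
      scan <- suppressMessages(stage_pair_novelty_scan(by_stage))
      data.table::fwrite(scan, p, sep = "\t")
    })
  }

  manifest <- file.path(out_dir, "manifest.txt")
  lines <- c(
    paste0("novelscope_version=", as.character(utils::packageVersion("novelscope"))),
    paste0("cnt_cutoff=", cnt_cutoff),
    paste0("tpm_threshold=", tpm_threshold),
    vapply(names(inputs), function(k) {
      paste0("input_", k, "=", inputs[[k]], ";md5=",
             unname(tools::md5sum(inputs[[k]])))
    }, character(1L)),
    vapply(names(outputs), function(k) {
      paste0("output_", k, "=", outputs[[k]], ";md5=",
             unname(tools::md5sum(outputs[[k]])))
    }, character(1L))
  )
  writeLines(lines, manifest)
  outputs$manifest <- manifest
  invisible(outputs)
}
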