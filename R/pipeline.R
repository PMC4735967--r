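# Pipeline orchestration: per-platform stage ordering, per-sample
# processing, demultiplexing of pooled inputs, and the three outputs
# (summary table, per-sample QC reports, per-sample Sanger-encoded FASTQ).

trim_params_from_config <- function(cfg) {
  trim_params(kmer = cfg[["trim.kmer"]],
              max_mismatch = cfg[["trim.max_mismatch"]],
              min_overlap = cfg[["trim.min_overlap"]],
              q_trim = cfg[["trim.q_trim"]],
              window = cfg[["trim.window"]])
}

filter_params_from_config <- function(cfg, platform) {
  thr <- cfg[["filter.complexity_threshold"]]
  filter_params(
    dup_mode = cfg[["filter.dup_mode"]],
    complexity_method = cfg[["filter.complexity_method"]],
    complexity_threshold = if (is.na(thr)) NULL else thr,
    min_mean_q = cfg[["filter.min_mean_q"]],
    min_len = if (platform == "sanger") cfg[["filter.min_len_sanger"]]
              else cfg[["filter.min_len"]],
    max_len = cfg[["filter.max_len"]],
    apply_complexity = platform != "sanger")
}

split_paths <- function(cell) {
  p <- strsplit(cell, ";", fixed = TRUE)[[1]]
  p[nzchar(p)]
}

# Convert one input file to a list of seq_records, per its detected format.
convert_file <- function(path, cfg, pair_role = "single") {
  fmt <- detect_format(path)
  switch(fmt,
    fastq = {
      enc <- cfg[["seqio.encoding"]]
      if (enc == "auto") enc <- detect_fastq_encoding(path)
      read_fastq(path, enc, pair_role = pair_role)
    },
    sff = lapply(read_sff(path), apply_sff_clips),
    fasta_qual = stop("FASTA input '", path,
                      "' needs its QUAL file (Qual column)"),
    stop("'", path, "': unsupported input format '", fmt, "'"))
}

read_sample_input <- function(row, cfg) {
  paths1 <- split_paths(row$Read1)
  if (row$Platform == "sanger") {
    chroms <- lapply(paths1, function(p) read_chromatogram(p))
    return(list(chroms = chroms, fwd = NULL, rev = NULL, paired = FALSE))
  }
  qual <- split_paths(row$Qual)
  if (length(qual)) {
    fwd <- read_fasta_qual(paths1[1], qual[1], pair_role = "single")
  } else {
    fwd <- convert_file(paths1[1], cfg, pair_role = "single")
  }
  paths2 <- split_paths(row$Read2)
  rev <- NULL
  if (length(paths2)) {
    rev <- convert_file(paths2[1], cfg, pair_role = "reverse")
    fwd <- lapply(fwd, function(r) { r$pair_role <- "forward"; r })
  }
  list(chroms = NULL, fwd = fwd, rev = rev, paired = !is.null(rev))
}

# Per-side trimming + per-read filter verdicts for one sample.
# Returns records, removal tally and stage log entries.
process_sample <- function(row, adapters, cfg, predemux = NULL) {
  platform <- row$Platform
  stages <- character(0)
  log_stage <- function(name, n_in, n_out) {
    stages <<- c(stages, sprintf("%s: %d -> %d", name, n_in, n_out))
  }
  tp <- trim_params_from_config(cfg)
  fp <- filter_params_from_config(cfg, platform)
  removed <- c(duplicate = 0L, complexity = 0L, min_len = 0L, max_len = 0L,
               min_mean_q = 0L, pair_lost = 0L)

  if (platform == "sanger") {
    input <- read_sample_input(row, cfg)
    ap <- ambiguity_params(ratio_threshold = cfg[["basecall.ratio_threshold"]],
                           recall_scope = cfg[["basecall.scope"]])
    reads <- lapply(input$chroms, refine_ambiguous_calls, params = ap)
    log_stage("base_calling", length(input$chroms), length(reads))
    log_stage("format_conversion", length(reads), length(reads))
    paired <- FALSE
    fwd <- reads
    rev <- NULL
  } else {
    if (!is.null(predemux)) {
      fwd <- predemux$fwd
      rev <- predemux$rev
      paired <- !is.null(rev)
      log_stage("format_conversion", predemux$n_pool, predemux$n_pool)
      log_stage("demultiplexing", predemux$n_pool, length(fwd))
    } else {
      input <- read_sample_input(row, cfg)
      fwd <- input$fwd
      rev <- input$rev
      paired <- input$paired
      log_stage("format_conversion", length(fwd) + length(rev),
                length(fwd) + length(rev))
    }
  }

  before <- accumulate_stats(c(fwd, rev))
  n_before <- length(fwd) + length(rev)

  # adapter/primer trimming
  n0 <- length(fwd) + length(rev)
  fwd <- lapply(fwd, trim_adapters_primers, specs = adapters, params = tp)
  if (paired) {
    rev <- lapply(rev, trim_adapters_primers, specs = adapters, params = tp)
  }
  log_stage("adapter_primer_trimming", n0, length(fwd) + length(rev))

  if (platform != "sanger") {
    # duplicate filtering (per sample, post-demultiplexing)
    n0 <- length(fwd) + length(rev)
    if (paired) {
      keys <- paste0(vapply(fwd, function(r) r$bases, character(1)), "|",
                     vapply(rev, function(r) r$bases, character(1)))
      keep <- duplicate_mask(keys, fp$dup_mode)
      removed["duplicate"] <- removed["duplicate"] + 2L * sum(!keep)
      fwd <- fwd[keep]
      rev <- rev[keep]
    } else {
      res <- filter_duplicates(fwd, fp$dup_mode)
      removed["duplicate"] <- removed["duplicate"] + res$removed_count
      fwd <- res$kept
    }
    log_stage("duplicate_filtering", n0, length(fwd) + length(rev))

    # contamination screening = low-complexity filter
    n0 <- length(fwd) + length(rev)
    flag_low <- function(r) {
      s <- complexity_score(r$bases, fp$complexity_method)
      if (fp$complexity_method == "dust") s > fp$complexity_threshold
      else s < fp$complexity_threshold
    }
    if (paired) {
      bad <- vapply(fwd, flag_low, logical(1)) |
        vapply(rev, flag_low, logical(1))
      removed["complexity"] <- removed["complexity"] + 2L * sum(bad)
      fwd <- fwd[!bad]
      rev <- rev[!bad]
    } else {
      bad <- vapply(fwd, flag_low, logical(1))
      removed["complexity"] <- removed["complexity"] + sum(bad)
      fwd <- fwd[!bad]
    }
    log_stage("contamination_filtering", n0, length(fwd) + length(rev))
  }

  # terminal N and low-quality end trimming
  n0 <- length(fwd) + length(rev)
  qtrim <- function(r) {
    trim_quality_ends(trim_terminal_ns(r), tp$q_trim, tp$window)
  }
  fwd <- lapply(fwd, qtrim)
  if (paired) rev <- lapply(rev, qtrim)
  log_stage("quality_trimming", n0, length(fwd) + length(rev))

  # read filtering (mean quality, length; complexity re-checked for NGS)
  n0 <- length(fwd) + length(rev)
  apply_read_filter <- function(reads) {
    verdicts <- lapply(reads, passes_filters, params = fp)
    pass <- vapply(verdicts, function(v) v$pass, logical(1))
    for (v in verdicts[!pass]) {
      crit <- if (v$criterion == "complexity") "complexity" else v$criterion
      removed[crit] <<- removed[crit] + 1L
    }
    reads[pass]
  }
  if (paired) {
    fwd_kept <- apply_read_filter(fwd)
    rev_kept <- apply_read_filter(rev)
    log_stage("read_filtering", n0, length(fwd_kept) + length(rev_kept))
    # paired-end consistency: drop the mate of every lost read
    n1 <- length(fwd_kept) + length(rev_kept)
    sync <- synchronize_pairs(fwd, rev, survivors = list(
      fwd = vapply(fwd_kept, function(r) r$read_id, character(1)),
      rev = vapply(rev_kept, function(r) r$read_id, character(1))))
    removed["pair_lost"] <- removed["pair_lost"] +
      n1 - (length(sync$fwd) + length(sync$rev))
    fwd <- sync$fwd
    rev <- sync$rev
    log_stage("pair_synchronization", n1, length(fwd) + length(rev))
  } else {
    fwd <- apply_read_filter(fwd)
    log_stage("read_filtering", n0, length(fwd))
  }

  after <- accumulate_stats(c(fwd, rev))
  log_stage("gc_assessment", after$n_reads, after$n_reads)

  list(fwd = fwd, rev = rev, paired = paired, before = before, after = after,
       removed = removed, n_before = n_before, stages = stages)
}

write_sample_outputs <- function(row, proc, out_dir) {
  pid <- row$Patient_ID
  if (proc$paired) {
    f1 <- file.path(out_dir, paste0(pid, "_R1.fastq"))
    f2 <- file.path(out_dir, paste0(pid, "_R2.fastq"))
    write_fastq_sanger(proc$fwd, f1)
    write_fastq_sanger(proc$rev, f2)
    fastq <- c(f1, f2)
  } else {
    f1 <- file.path(out_dir, paste0(pid, ".fastq"))
    write_fastq_sanger(proc$fwd, f1)
    fastq <- f1
  }
  rb <- file.path(out_dir, paste0(pid, "_before.html"))
  ra <- file.path(out_dir, paste0(pid, "_after.html"))
  render_qc_report(proc$before, proc$after, rb,
                   title = paste(pid, "before QC"))
  render_qc_report(proc$before, proc$after, ra,
                   title = paste(pid, "after QC"))
  list(fastq = fastq, report_before = rb, report_after = ra)
}

#' Run the full QC pipeline over a sample manifest
#'
#' Per sample, executes the platform-appropriate stage order. Sanger rows:
#' read traces, refine ambiguous calls, convert, trim primers/adapters, trim
#' terminal Ns and low-quality ends, filter, report. NGS rows: convert,
#' demultiplex (unless already demultiplexed), trim adapters/primers, remove
#' duplicates, screen low-complexity reads, trim ends, filter, synchronise
#' pairs, report. Samples are processed independently (and concurrently when
#' `workers > 1`); results are identical to serial execution regardless of
#' worker count. A failing sample is recorded as failed in the summary and
#' the other samples proceed.
#'
#' @param manifest A [parse_target_file()] manifest.
#' @param adapters List of [adapter_spec()]s (see [parse_adapter_file()]).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param workers Number of concurrent sample workers (default: config).
#' @return A `pipeline_run` list: `results` (one per sample, manifest
#'   order), `summary_html`, `summary_tsv`, `n_failed`.
#' @export
run_pipeline <- function(manifest, adapters = list(),
                         config = pipeline_config(), out_dir,
                         workers = config[["run.workers"]]) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(config_echo_lines(config),
             file.path(out_dir, "effective_options.txt"))

  # demultiplex pooled NGS inputs once per pooled file group
  predemux <- vector("list", nrow(manifest))
  pooled <- which(nzchar(manifest$MID) & !manifest$Demultiplexed &
                    manifest$Platform != "sanger")
  if (length(pooled)) {
    for (key in unique(manifest$Read1[pooled])) {
      rows <- pooled[manifest$Read1[pooled] == key]
      table <- barcode_table(manifest$Patient_ID[rows], manifest$MID[rows],
                             max_mismatch = config[["demux.max_mismatch"]])
      input <- read_sample_input(manifest[rows[1], , drop = FALSE], config)
      reads <- if (input$paired) list(fwd = input$fwd, rev = input$rev)
               else input$fwd
      counts <- demultiplex(reads, table)
      bins <- attr(counts, "bins")
      bins_rev <- attr(counts, "bins_rev")
      n_pool <- if (input$paired) 2L * length(input$fwd) else length(input$fwd)
      for (j in rows) {
        pid <- manifest$Patient_ID[j]
        predemux[[j]] <- list(
          fwd = bins[[pid]],
          rev = if (input$paired) bins_rev[[pid]] else NULL,
          n_pool = n_pool)
      }
    }
  }

  one_sample <- function(i) {
    row <- manifest[i, , drop = FALSE]
    extra <- as.list(row[1, attr(manifest, "extra_cols"), drop = FALSE])
    tryCatch({
      proc <- process_sample(row, adapters, config, predemux[[i]])
      outs <- write_sample_outputs(row, proc, out_dir)
      n_after <- proc$after$n_reads
      list(patient_id = row$Patient_ID, status = "ok",
           reads_before = proc$n_before, reads_after = n_after,
           gc_before = proc$before$gc_percent,
           gc_after = proc$after$gc_percent,
           removed = proc$removed, stages = proc$stages,
           fastq = outs$fastq, report_before = outs$report_before,
           report_after = outs$report_after, extra = extra)
    }, error = function(e) {
      list(patient_id = row$Patient_ID, status = "failed",
           reads_before = 0L, reads_after = 0L,
           gc_before = 0, gc_after = 0,
           removed = NULL, stages = character(0),
           fastq = NULL, report_before = NULL, report_after = NULL,
           extra = extra, error = conditionMessage(e))
    })
  }

  results <- if (workers > 1L) {
    parallel::mclapply(seq_len(nrow(manifest)), one_sample,
                       mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(seq_len(nrow(manifest)), one_sample)
  }

  summary_html <- file.path(out_dir, "summary.html")
  render_summary_table(results, summary_html, manifest = manifest)
  structure(list(results = results,
                 summary_html = summary_html,
                 summary_tsv = file.path(out_dir, "summary.tsv"),
                 n_failed = sum(vapply(results, function(r) r$status,
                                       character(1)) == "failed")),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d samples, %d failed; summary: %s\n",
              length(x$results), x$n_failed, x$summary_tsv))
  invisible(x)
}
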