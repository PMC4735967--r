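#' Accumulate QC statistics over a read stream
#'
#' Single pass over the reads, computing read/base counts, the per-position
#' quality distribution (count, mean and nearest-rank quartiles), the read
#' length histogram, mean GC content, sequence duplication levels and
#' overrepresented sequences (frequency above 0.1% of reads, capped list).
#'
#' GC content per read is `100 * (G + C + S) / (A + C + G + T + S + W)`
#' (S counts as G/C, W as A/T; other ambiguity codes and N are excluded from
#' the denominator), averaged over reads with a non-empty denominator. An
#' empty stream reports `gc_percent = 0` with `gc_defined = FALSE`.
#'
#' @param reads List of [seq_record()]s (may be empty).
#' @param overrep_cap Maximum number of overrepresented sequences kept.
#' @return A `qc_stats` object.
#' @export
accumulate_stats <- function(reads, overrep_cap = 20L) {
  n <- length(reads)
  if (n == 0L) {
    return(structure(list(
      n_reads = 0L, n_bases = 0, per_position = empty_per_position(),
      length_hist = integer(0), gc_percent = 0, gc_defined = FALSE,
      duplication_hist = integer(0),
      overrepresented = data.frame(sequence = character(0),
                                   count = integer(0),
                                   percent = numeric(0))),
      class = "qc_stats"))
  }
  seqs <- vapply(reads, function(r) r$bases, character(1))
  lens <- nchar(seqs)
  maxlen <- max(lens)
  qmat <- matrix(0L, nrow = max(maxlen, 1L), ncol = 94L)
  for (r in reads) {
    q <- r$quals
    if (length(q)) {
      idx <- cbind(seq_along(q), q + 1L)
      qmat[idx] <- qmat[idx] + 1L
    }
  }
  counts <- rowSums(qmat)
  used <- which(counts > 0)
  per_position <- if (length(used)) {
    qs <- 0:93
    means <- as.vector(qmat %*% qs) / pmax(counts, 1)
    quart <- t(vapply(used, function(p) {
      nearest_rank_quartiles(qmat[p, ], counts[p])
    }, numeric(3)))
    data.frame(position = used, count = counts[used], mean = means[used],
               q25 = quart[, 1], median = quart[, 2], q75 = quart[, 3])
  } else {
    empty_per_position()
  }
  gc_n <- nchar(gsub("[^GCS]", "", seqs))
  den <- nchar(gsub("[^ACGTSW]", "", seqs))
  gc_reads <- 100 * gc_n[den > 0] / den[den > 0]
  gc_defined <- length(gc_reads) > 0
  lh <- table(lens)
  length_hist <- stats::setNames(as.integer(lh), names(lh))
  seq_tab <- table(seqs)
  dh <- table(as.integer(seq_tab))
  duplication_hist <- stats::setNames(as.integer(dh), names(dh))
  thr <- 0.001 * n
  over_idx <- which(as.integer(seq_tab) > thr)
  over <- data.frame(sequence = names(seq_tab)[over_idx],
                     count = as.integer(seq_tab)[over_idx],
                     stringsAsFactors = FALSE)
  over <- over[order(-over$count, over$sequence), , drop = FALSE]
  over <- utils::head(over, overrep_cap)
  over$percent <- 100 * over$count / n
  rownames(over) <- NULL
  structure(list(
    n_reads = n, n_bases = sum(lens), per_position = per_position,
    length_hist = length_hist,
    gc_percent = if (gc_defined) mean(gc_reads) else 0,
    gc_defined = gc_defined,
    duplication_hist = duplication_hist,
    overrepresented = over), class = "qc_stats")
}

empty_per_position <- function() {
  data.frame(position = integer(0), count = numeric(0), mean = numeric(0),
             q25 = numeric(0), median = numeric(0), q75 = numeric(0))
}

# nearest-rank quartiles from a per-position quality histogram
# (counts over scores 0..93)
nearest_rank_quartiles <- function(counts, n) {
  cum <- cumsum(counts)
  vapply(c(0.25, 0.5, 0.75), function(p) {
    r <- max(1, ceiling(p * n))
    which(cum >= r)[1] - 1
  }, numeric(1))
}

#' @export
print.qc_stats <- function(x, ...) {
  cat(sprintf("<qc_stats> %d reads, %.0f bases, GC %.2f%%%s\n",
              x$n_reads, x$n_bases, x$gc_percent,
              if (!x$gc_defined) " (undefined: no reads)" else ""))
  invisible(x)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, digits = 3, escape = TRUE) {
  if (!nrow(df)) return("<p><em>no data</em></p>")
  fmt <- function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      format(round(col, digits), trim = TRUE, scientific = FALSE)
    } else {
      as.character(col)
    }
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  esc <- if (escape) html_escape else identity
  head_row <- paste0("<tr>", paste0("<th>", esc(colnames(df)),
                                    "</th>", collapse = ""), "</tr>")
  body <- apply(cells, 1, function(rw) {
    paste0("<tr>", paste0("<td>", esc(rw), "</td>", collapse = ""),
           "</tr>")
  })
  paste0("<table border='1' cellspacing='0' cellpadding='3'>\n", head_row,
         "\n", paste(body, collapse = "\n"), "\n</table>")
}

stats_tables <- function(stats) {
  lh <- data.frame(length = as.integer(names(stats$length_hist)),
                   count = as.integer(stats$length_hist))
  dh <- data.frame(copies = as.integer(names(stats$duplication_hist)),
                   distinct_sequences = as.integer(stats$duplication_hist))
  list(per_position = stats$per_position, length_hist = lh,
       duplication = dh, overrepresented = stats$overrepresented)
}

stats_section_html <- function(stats, label) {
  tabs <- stats_tables(stats)
  paste0(
    "<h2 id='", label, "'>", tools::toTitleCase(label), " QC</h2>\n",
    if (stats$n_reads == 0L) "<p><strong>0 reads survived</strong></p>\n" else "",
    sprintf("<p>Reads: %d &middot; Bases: %.0f &middot; Mean GC: %.2f%%</p>\n",
            stats$n_reads, stats$n_bases, stats$gc_percent),
    "<h3>Per-position quality</h3>\n", html_table(tabs$per_position), "\n",
    "<h3>Read length distribution</h3>\n", html_table(tabs$length_hist), "\n",
    "<h3>Sequence duplication levels</h3>\n", html_table(tabs$duplication), "\n",
    "<h3>Overrepresented sequences</h3>\n", html_table(tabs$overrepresented),
    "\n")
}

#' Render a before/after QC report
#'
#' Writes a standalone HTML report with per-position quality tables, length
#' histogram, GC content, duplication levels and overrepresented sequences
#' for the before- and after-QC statistics. Every numeric table is also
#' emitted as a tab-separated sidecar file (one per table family, with a
#' `phase` column) next to the HTML. Rendered numbers are taken verbatim
#' from the [accumulate_stats()] output.
#'
#' @param before,after `qc_stats` objects.
#' @param out_path Output HTML path.
#' @param title Report title.
#' @return `out_path`, invisibly.
#' @export
render_qc_report <- function(before, after, out_path, title = "QC report") {
  stem <- sub("\\.html?$", "", out_path)
  add_phase <- function(df, phase) {
    cbind(phase = rep(phase, nrow(df)), df)
  }
  for (fam in c("per_position", "length_hist", "duplication",
                "overrepresented")) {
    tb <- rbind(add_phase(stats_tables(before)[[fam]], "before"),
                add_phase(stats_tables(after)[[fam]], "after"))
    utils::write.table(tb, paste0(stem, ".", fam, ".tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'><title>",
    html_escape(title), "</title></head><body>\n<h1>", html_escape(title),
    "</h1>\n",
    stats_section_html(before, "before"),
    stats_section_html(after, "after"),
    "</body></html>\n")
  writeLines(html, out_path)
  invisible(out_path)
}

#' Render the cohort summary table
#'
#' One row per sample with the manifest's experimental/patient columns, read
#' and GC content before and after QC, and hyperlinks to the per-sample QC
#' reports and final FASTQ files. Written as HTML plus a tab-separated twin
#' (same path with `.tsv`).
#'
#' @param results List of sample-result lists as produced by
#'   [run_pipeline()] (each with at least `patient_id`, `reads_before`,
#'   `reads_after`, `gc_before`, `gc_after`, `status`, and file fields).
#' @param out_path Output HTML path.
#' @param manifest Optional [parse_target_file()] manifest; when given, the
#'   result set must cover exactly its patient ids.
#' @return `out_path`, invisibly.
#' @export
render_summary_table <- function(results, out_path, manifest = NULL) {
  ids <- vapply(results, function(r) r$patient_id, character(1))
  if (!is.null(manifest)) {
    missing <- setdiff(manifest$Patient_ID, ids)
    if (length(missing)) {
      stop("no result for patient id(s): ", paste(missing, collapse = ", "))
    }
  }
  rows <- lapply(results, function(r) {
    extra <- r$extra
    base <- data.frame(
      Patient_ID = r$patient_id,
      status = r$status,
      reads_before = r$reads_before,
      reads_after = r$reads_after,
      gc_before = round(r$gc_before, 4),
      gc_after = round(r$gc_after, 4),
      report_before = if (is.null(r$report_before)) "" else basename(r$report_before),
      report_after = if (is.null(r$report_after)) "" else basename(r$report_after),
      fastq = if (is.null(r$fastq)) "" else
        paste(basename(unlist(r$fastq)), collapse = ";"),
      stringsAsFactors = FALSE)
    if (!is.null(extra) && length(extra)) {
      base <- cbind(base, as.data.frame(as.list(extra),
                                        stringsAsFactors = FALSE,
                                        check.names = FALSE))
    }
    base
  })
  all_cols <- Reduce(union, lapply(rows, colnames))
  rows <- lapply(rows, function(d) {
    for (cc in setdiff(all_cols, colnames(d))) d[[cc]] <- ""
    d[all_cols]
  })
  df <- do.call(rbind, rows)
  tsv_path <- sub("\\.html?$", ".tsv", out_path)
  if (tsv_path == out_path) tsv_path <- paste0(out_path, ".tsv")
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  linked <- df
  link_cols <- c("report_before", "report_after")
  for (col in setdiff(colnames(df), c(link_cols, "fastq"))) {
    linked[[col]] <- html_escape(as.character(df[[col]]))
  }
  for (col in link_cols) {
    esc <- html_escape(df[[col]])
    linked[[col]] <- ifelse(nzchar(df[[col]]),
                            sprintf("<a href='%s'>%s</a>", esc, esc), "")
  }
  linked$fastq <- vapply(strsplit(df$fastq, ";", fixed = TRUE), function(fs) {
    fs <- html_escape(fs[nzchar(fs)])
    paste(sprintf("<a href='%s'>%s</a>", fs, fs), collapse = " ")
  }, character(1))
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset='utf-8'>",
    "<title>QC summary</title></head><body>\n<h1>QC summary</h1>\n",
    html_table(linked, escape = FALSE),
    "\n</body></html>\n")
  writeLines(html, out_path)
  invisible(out_path)
}
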