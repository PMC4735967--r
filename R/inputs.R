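# Target-file, adapter-file and options-file parsing.

TARGET_KNOWN_COLS <- c("Patient_ID", "Platform", "Read1", "Read2", "Qual",
                       "MID", "Demultiplexed")

PLATFORMS <- c("sanger", "illumina", "454", "iontorrent")

#' Parse the Target file (sample manifest)
#'
#' Tab-separated with a header row. `Patient_ID` is mandatory and must be
#' unique. Recognised optional columns: `Platform` (sanger / illumina / 454
#' / iontorrent; inferred from the first input file's format when absent),
#' `Read1` (input path; Sanger rows may list several trace files separated
#' by `;`), `Read2` (reverse-mate path), `Qual` (QUAL path pairing a FASTA
#' `Read1`), `MID` (barcode), `Demultiplexed` (true/false; defaults to true
#' unless a MID is given). Any other column is carried verbatim into the
#' summary table. Relative paths are resolved against the Target file's
#' directory, and all referenced paths must exist.
#'
#' @param path Target file path.
#' @return A `sample_manifest` data frame (one row per sample) with the
#'   extra-column names in attribute `"extra_cols"`.
#' @export
parse_target_file <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = NULL)
  if (!"Patient_ID" %in% colnames(df)) {
    stop("Target file '", path, "': missing mandatory column Patient_ID")
  }
  dup <- unique(df$Patient_ID[duplicated(df$Patient_ID)])
  if (length(dup)) {
    stop("Target file '", path, "': duplicate Patient_ID: ",
         paste(dup, collapse = ", "))
  }
  if (any(!nzchar(df$Patient_ID))) {
    stop("Target file '", path, "': empty Patient_ID")
  }
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(!nzchar(p) | grepl("^/", p), p, file.path(base_dir, p))
  }
  for (col in c("Read1", "Read2", "Qual")) {
    if (!col %in% colnames(df)) df[[col]] <- ""
    df[[col]] <- vapply(df[[col]], function(cell) {
      if (!nzchar(cell)) return("")
      paste(resolve(strsplit(cell, ";", fixed = TRUE)[[1]]), collapse = ";")
    }, character(1), USE.NAMES = FALSE)
  }
  if (!"MID" %in% colnames(df)) df$MID <- ""
  df$MID <- toupper(df$MID)
  if (!"Demultiplexed" %in% colnames(df)) df$Demultiplexed <- ""
  df$Demultiplexed <- ifelse(
    nzchar(df$Demultiplexed),
    tolower(df$Demultiplexed) %in% c("true", "yes", "1"),
    !nzchar(df$MID))
  missing_paths <- character(0)
  for (i in seq_len(nrow(df))) {
    paths <- unlist(strsplit(c(df$Read1[i], df$Read2[i], df$Qual[i]), ";",
                             fixed = TRUE))
    paths <- paths[nzchar(paths)]
    if (!length(paths)) {
      stop("Target file '", path, "': row '", df$Patient_ID[i],
           "' lists no input files")
    }
    missing_paths <- c(missing_paths, paths[!file.exists(paths)])
  }
  if (length(missing_paths)) {
    stop("Target file '", path, "': missing input file(s): ",
         paste(unique(missing_paths), collapse = ", "))
  }
  if (!"Platform" %in% colnames(df)) df$Platform <- ""
  df$Platform <- tolower(df$Platform)
  for (i in seq_len(nrow(df))) {
    if (!nzchar(df$Platform[i])) {
      first <- strsplit(df$Read1[i], ";", fixed = TRUE)[[1]][1]
      df$Platform[i] <- switch(detect_format(first),
                               ab1 = , scf = "sanger",
                               sff = , fasta_qual = "454",
                               fastq = "illumina",
                               stop("cannot infer platform for '",
                                    df$Patient_ID[i], "' from '", first, "'"))
    }
    if (!df$Platform[i] %in% PLATFORMS) {
      stop("Target file '", path, "': unknown platform '", df$Platform[i],
           "' for '", df$Patient_ID[i], "'")
    }
  }
  extra <- setdiff(colnames(df), TARGET_KNOWN_COLS)
  structure(df, extra_cols = extra,
            class = c("sample_manifest", "data.frame"))
}

#' Parse the Adapter-Primer file
#'
#' Tab-separated, four columns per line: feature-type (`adapter` or
#' `primer`), id, forward sequence, reverse sequence (either sequence may be
#' empty, not both). An absent file yields an empty feature set, turning the
#' trimming stage into a no-op.
#'
#' @param path Adapter-Primer file path, or `NULL`/nonexistent for none.
#' @return List of [adapter_spec()]s.
#' @export
parse_adapter_file <- function(path) {
  if (is.null(path) || !nzchar(path) || !file.exists(path)) return(list())
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  specs <- vector("list", 0L)
  for (i in seq_along(lines)) {
    ntab <- lengths(regmatches(lines[i], gregexpr("\t", lines[i], fixed = TRUE)))
    if (ntab != 3L) {
      stop("Adapter-Primer file '", path, "', line ", i,
           ": expected 4 tab-separated columns ",
           "(feature-type, id, forward, reverse), found ", ntab + 1L)
    }
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    length(fields) <- 4L
    fields[is.na(fields)] <- ""
    specs[[length(specs) + 1L]] <-
      adapter_spec(trimws(fields[1]), trimws(fields[2]),
                   trimws(fields[3]), trimws(fields[4]))
  }
  specs
}

option_schema <- function() {
  list(
    "basecall.ratio_threshold" = list(type = "numeric", default = 0.5),
    "basecall.scope" = list(type = "choice", default = "n_only",
                            choices = c("n_only", "all_positions")),
    "demux.max_mismatch" = list(type = "integer", default = 0L),
    "trim.kmer" = list(type = "integer", default = 10L),
    "trim.max_mismatch" = list(type = "integer", default = 2L),
    "trim.min_overlap" = list(type = "integer", default = 5L),
    "trim.q_trim" = list(type = "numeric", default = 20),
    "trim.window" = list(type = "integer", default = 5L),
    "filter.dup_mode" = list(type = "modes", default = "exact"),
    "filter.complexity_method" = list(type = "choice", default = "dust",
                                      choices = c("dust", "entropy")),
    "filter.complexity_threshold" = list(type = "numeric", default = NA_real_),
    "filter.min_mean_q" = list(type = "numeric", default = 20),
    "filter.min_len" = list(type = "integer", default = 50L),
    "filter.min_len_sanger" = list(type = "integer", default = 100L),
    "filter.max_len" = list(type = "numeric", default = Inf),
    "seqio.encoding" = list(type = "choice", default = "auto",
                            choices = c("auto", "phred33", "phred64")),
    "run.workers" = list(type = "integer", default = 1L)
  )
}

coerce_option <- function(key, value, entry) {
  switch(entry$type,
    numeric = {
      v <- if (tolower(value) %in% c("inf", "unlimited")) Inf
           else if (toupper(value) == "NA") return(NA_real_)
           else suppressWarnings(as.numeric(value))
      if (is.na(v) && !is.na(value)) {
        stop("option '", key, "': cannot parse '", value, "' as a number")
      }
      v
    },
    integer = {
      v <- suppressWarnings(as.integer(value))
      if (is.na(v)) {
        stop("option '", key, "': cannot parse '", value, "' as an integer")
      }
      v
    },
    choice = {
      if (!value %in% entry$choices) {
        stop("option '", key, "': '", value, "' is not one of ",
             paste(entry$choices, collapse = "/"))
      }
      value
    },
    modes = {
      modes <- trimws(strsplit(value, ",", fixed = TRUE)[[1]])
      bad <- setdiff(modes, c("exact", "prefix", "revcomp"))
      if (length(bad)) {
        stop("option '", key, "': unknown duplicate mode(s) ",
             paste(bad, collapse = ", "))
      }
      modes
    })
}

#' Parse the Options file
#'
#' Flat `key = value` text with `#` comments. Every key must belong to the
#' closed schema (unknown keys are fatal, catching typos); omitted keys take
#' their defaults. [run_pipeline()] echoes the effective configuration next
#' to its outputs so that a run can be reproduced from the echo alone.
#'
#' @param path Options file path, or `NULL` for all defaults.
#' @return A `pipeline_config` named list.
#' @seealso [pipeline_config()] for programmatic construction.
#' @export
parse_options <- function(path = NULL) {
  overrides <- list()
  if (!is.null(path) && nzchar(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq < 0) stop("options file: cannot parse line '", ln, "'")
      key <- trimws(substr(ln, 1, eq - 1))
      value <- trimws(substr(ln, eq + 1, nchar(ln)))
      overrides[[key]] <- value
    }
  }
  do.call(pipeline_config, overrides)
}

#' Build a pipeline configuration
#'
#' @param ... `key = value` overrides using the dotted option names of the
#'   options-file schema (e.g. `` `filter.min_mean_q` = 25 ``). Unknown keys
#'   are fatal.
#' @return A `pipeline_config` named list of validated settings.
#' @export
pipeline_config <- function(...) {
  schema <- option_schema()
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(schema))
  if (length(unknown)) {
    stop("unknown option key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- lapply(schema, function(e) e$default)
  for (key in names(overrides)) {
    val <- overrides[[key]]
    cfg[[key]] <- if (is.character(val) && length(val) == 1L) {
      coerce_option(key, val, schema[[key]])
    } else {
      val
    }
  }
  structure(cfg, class = "pipeline_config")
}

config_echo_lines <- function(cfg) {
  vapply(names(cfg), function(key) {
    v <- cfg[[key]]
    paste0(key, " = ", paste(format(v, scientific = FALSE), collapse = ","))
  }, character(1))
}
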