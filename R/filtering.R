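#' Read-filtering parameters
#'
#' @param dup_mode Character subset of `c("exact", "prefix", "revcomp")`
#'   (default `"exact"`): duplicate definitions applied by
#'   [filter_duplicates()].
#' @param complexity_method `"dust"` or `"entropy"`.
#' @param complexity_threshold On the 0-100 score scale; a read fails when
#'   its DUST score exceeds the threshold (default 7) or its entropy score
#'   falls below it (default 30).
#' @param min_mean_q Minimum mean Phred quality (default 20).
#' @param min_len,max_len Read length bounds (defaults 50 and unlimited; the
#'   pipeline raises `min_len` to 100 for Sanger samples).
#' @param apply_complexity Whether the complexity criterion participates in
#'   [passes_filters()]; the pipeline disables it for Sanger samples, where
#'   duplicate/contamination screening does not apply.
#' @return A `filter_params` list.
#' @export
filter_params <- function(dup_mode = "exact",
                          complexity_method = c("dust", "entropy"),
                          complexity_threshold = NULL,
                          min_mean_q = 20, min_len = 50L, max_len = Inf,
                          apply_complexity = TRUE) {
  complexity_method <- match.arg(complexity_method)
  dup_mode <- match.arg(dup_mode, c("exact", "prefix", "revcomp"),
                        several.ok = TRUE)
  if (is.null(complexity_threshold)) {
    complexity_threshold <- if (complexity_method == "dust") 7 else 30
  }
  if (complexity_threshold < 0 || complexity_threshold > 100) {
    stop("complexity_threshold must be in [0, 100]")
  }
  if (min_len > max_len) stop("min_len must be <= max_len")
  structure(list(dup_mode = dup_mode,
                 complexity_method = complexity_method,
                 complexity_threshold = as.numeric(complexity_threshold),
                 min_mean_q = as.numeric(min_mean_q),
                 min_len = as.integer(min_len),
                 max_len = max_len,
                 apply_complexity = isTRUE(apply_complexity)),
            class = "filter_params")
}

# Streaming duplicate mask over arbitrary keys; first occurrence is always
# kept. Returns a logical keep vector.
duplicate_mask <- function(keys, dup_mode) {
  n <- length(keys)
  keep <- logical(n)
  kept_keys <- character(0)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  seen_rc <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    k <- keys[i]
    dup <- FALSE
    if ("exact" %in% dup_mode && !is.null(seen[[k]])) dup <- TRUE
    if (!dup && "revcomp" %in% dup_mode && !is.null(seen_rc[[k]])) dup <- TRUE
    if (!dup && "prefix" %in% dup_mode && length(kept_keys)) {
      longer <- nchar(kept_keys) > nchar(k)
      if (any(longer) && any(startsWith(kept_keys[longer], k))) dup <- TRUE
    }
    if (!dup) {
      keep[i] <- TRUE
      kept_keys <- c(kept_keys, k)
      seen[[k]] <- TRUE
      seen_rc[[revcomp(k)]] <- TRUE
    }
  }
  keep
}

#' Remove duplicate reads
#'
#' Streaming duplicate removal; the first occurrence is always kept. Modes
#' (combinable): `exact` collapses identical base strings; `prefix` removes
#' a read equal to the 5' prefix of an already-kept longer read; `revcomp`
#' removes a read identical to the reverse complement of a kept read.
#'
#' @param reads List of [seq_record()]s.
#' @param dup_mode Subset of `c("exact", "prefix", "revcomp")`.
#' @param keys Optional explicit duplicate keys (e.g. concatenated mate
#'   sequences for paired input); defaults to each read's base string.
#' @return `list(kept = <records>, keep = <logical>, removed_count = <int>)`.
#' @export
filter_duplicates <- function(reads, dup_mode = "exact", keys = NULL) {
  dup_mode <- match.arg(dup_mode, c("exact", "prefix", "revcomp"),
                        several.ok = TRUE)
  if (is.null(keys)) {
    keys <- vapply(reads, function(r) r$bases, character(1))
  }
  keep <- duplicate_mask(keys, dup_mode)
  list(kept = reads[keep], keep = keep, removed_count = sum(!keep))
}

kmer3_counts <- function(bases) {
  l <- nchar(bases)
  if (l < 3L) return(integer(0))
  table(substring(bases, 1:(l - 2L), 3:l))
}

#' Low-complexity score of a sequence
#'
#' `dust`: over overlapping 3-mers, `raw = sum c_t (c_t - 1) / 2` with `c_t`
#' the count of 3-mer `t`, scaled by the maximum
#' `(L - 2)(L - 3) / 2` to 0-100; homopolymers score 100, a sequence with
#' all-distinct 3-mers scores 0. `entropy`: Shannon entropy of the 3-mer
#' distribution normalised by `log(min(L - 2, 64))`, scaled to 0-100;
#' homopolymers score 0. Sequences shorter than 3 bases score 0 under both.
#'
#' @param bases IUPAC base string.
#' @param method `"dust"` or `"entropy"`.
#' @return Score in `[0, 100]`.
#' @export
complexity_score <- function(bases, method = c("dust", "entropy")) {
  method <- match.arg(method)
  bases <- toupper(bases)
  if (nzchar(bases) && !grepl("^[ACGTUNRYSWKMBDHV]*$", bases)) {
    stop("complexity_score: non-IUPAC characters in sequence")
  }
  l <- nchar(bases)
  if (l < 3L) return(0)
  counts <- as.numeric(kmer3_counts(bases))
  if (method == "dust") {
    raw <- sum(counts * (counts - 1) / 2)
    maxraw <- (l - 2) * (l - 3) / 2
    if (maxraw <= 0) return(0)
    100 * raw / maxraw
  } else {
    p <- counts / sum(counts)
    h <- -sum(p * log(p)) + 0  # + 0 normalises IEEE negative zero
    norm <- log(min(l - 2, 64))
    if (norm <= 0) return(0)
    100 * h / norm
  }
}

#' Test a read against the quality/length/complexity thresholds
#'
#' A read passes when its mean quality is at least `min_mean_q`, its length
#' lies in `[min_len, max_len]`, and (when enabled) its complexity score is
#' acceptable. The first failed criterion is reported for QC accounting, in
#' the order `min_len`, `max_len`, `min_mean_q`, `complexity`.
#'
#' @param record A [seq_record()].
#' @param params A [filter_params()].
#' @return `list(pass = <logical>, criterion = <name or NA>)`.
#' @export
passes_filters <- function(record, params = filter_params()) {
  n <- record_length(record)
  if (n < params$min_len) {
    return(list(pass = FALSE, criterion = "min_len"))
  }
  if (n > params$max_len) {
    return(list(pass = FALSE, criterion = "max_len"))
  }
  if (n == 0L || mean(record$quals) < params$min_mean_q) {
    return(list(pass = FALSE, criterion = "min_mean_q"))
  }
  if (params$apply_complexity) {
    s <- complexity_score(record$bases, params$complexity_method)
    bad <- if (params$complexity_method == "dust") {
      s > params$complexity_threshold
    } else {
      s < params$complexity_threshold
    }
    if (bad) return(list(pass = FALSE, criterion = "complexity"))
  }
  list(pass = TRUE, criterion = NA_character_)
}

strip_mate_suffix <- function(ids) {
  sub("/[12]$", "", sub("\\s.*$", "", ids))
}

#' Synchronise paired-end reads after filtering
#'
#' If one read of a pair is lost during trimming or filtering, its mate must
#' also be excluded. Identifiers are normalised by stripping `/1`, `/2` and
#' space-delimited (Casava-style) suffixes. The output contains exactly the
#' pairs whose both mates survived, in the forward stream's original order,
#' so the forward and reverse output identifier sequences are identical.
#'
#' @param fwd,rev Lists of [seq_record()]s sharing an id universe.
#' @param survivors Optional `list(fwd = <ids>, rev = <ids>)` of normalised
#'   ids that survived per side; defaults to all ids present in each stream.
#' @return `list(fwd = <records>, rev = <records>)`.
#' @export
synchronize_pairs <- function(fwd, rev, survivors = NULL) {
  fid <- strip_mate_suffix(vapply(fwd, function(r) r$read_id, character(1)))
  rid <- strip_mate_suffix(vapply(rev, function(r) r$read_id, character(1)))
  for (side in list(c("forward", fid), c("reverse", rid))) {
    ids <- side[-1]
    if (anyDuplicated(ids)) {
      stop("duplicate read id '", ids[anyDuplicated(ids)],
           "' in ", side[1], " stream")
    }
  }
  surv_f <- if (is.null(survivors)) fid else strip_mate_suffix(survivors$fwd)
  surv_r <- if (is.null(survivors)) rid else strip_mate_suffix(survivors$rev)
  keep_ids <- fid[fid %in% surv_f & fid %in% surv_r & fid %in% rid]
  list(fwd = fwd[match(keep_ids, fid)],
       rev = rev[match(keep_ids, rid)])
}
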