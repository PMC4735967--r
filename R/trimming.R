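#' Trimming parameters
#'
#' @param kmer Seed length for adapter matching (default 10, minimum 4).
#' @param max_mismatch Mismatches allowed across a full adapter alignment
#'   (default 2); partial alignments scale as
#'   `ceiling(max_mismatch * aligned_length / adapter_length)`.
#' @param min_overlap Minimum length of a 3'-terminal partial adapter
#'   occurrence (default 5).
#' @param q_trim Phred threshold for end trimming (default 20).
#' @param window Trailing-window size for quality trimming (default 5).
#' @return A `trim_params` list.
#' @export
trim_params <- function(kmer = 10L, max_mismatch = 2L, min_overlap = 5L,
                        q_trim = 20, window = 5L) {
  if (kmer < 4L) stop("kmer must be >= 4")
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  if (q_trim < 0 || q_trim > 93) stop("q_trim must be in [0, 93]")
  if (window < 1L) stop("window must be >= 1")
  structure(list(kmer = as.integer(kmer),
                 max_mismatch = as.integer(max_mismatch),
                 min_overlap = as.integer(min_overlap),
                 q_trim = as.numeric(q_trim),
                 window = as.integer(window)),
            class = "trim_params")
}

#' Adapter/primer feature specification
#'
#' @param feature_type `"adapter"` or `"primer"`.
#' @param feature_id Feature identifier.
#' @param forward_seq,reverse_seq ACGT strings; at least one non-empty.
#' @return An `adapter_spec` list.
#' @export
adapter_spec <- function(feature_type = c("adapter", "primer"), feature_id,
                         forward_seq = "", reverse_seq = "") {
  feature_type <- match.arg(feature_type)
  forward_seq <- toupper(forward_seq)
  reverse_seq <- toupper(reverse_seq)
  if (!nzchar(forward_seq) && !nzchar(reverse_seq)) {
    stop("feature '", feature_id, "': both sequences empty")
  }
  for (s in c(forward_seq, reverse_seq)) {
    if (nzchar(s) && !grepl("^[ACGT]+$", s)) {
      stop("feature '", feature_id, "': sequence must be over ACGT, got '",
           s, "'")
    }
  }
  structure(list(feature_type = feature_type,
                 feature_id = as.character(feature_id),
                 forward_seq = forward_seq, reverse_seq = reverse_seq),
            class = "adapter_spec")
}

count_mismatches <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# Evaluate one ungapped placement of `adapter` starting at 0-based offset
# `o` in `read`; returns mismatch count and aligned length, or NULL if the
# placement is not admissible under min_overlap.
align_at_offset <- function(read, adapter, o, la, lr, min_overlap) {
  aligned <- min(la, lr - o)
  if (aligned < la && aligned < min_overlap) return(NULL)
  if (aligned <= 0L) return(NULL)
  mm <- count_mismatches(substr(read, o + 1L, o + aligned),
                         substr(adapter, 1L, aligned))
  list(start = o + 1L, end = o + aligned, aligned = aligned, mismatches = mm)
}

#' Locate the best adapter occurrence in a read
#'
#' Candidate placements are seeded by exact k-mer matches between adapter
#' and read (every adapter k-mer is indexed), each seed extended to a full
#' ungapped alignment of the adapter at that offset; every 3'-terminal
#' partial occurrence of the adapter prefix with length at least
#' `min_overlap` is also evaluated. An N in the read counts as a mismatch.
#' A placement is accepted when its mismatch count is at most
#' `ceiling(max_mismatch * aligned_length / adapter_length)`; among accepted
#' placements the fewest mismatches wins, ties going to the leftmost.
#'
#' Note the k-mer seeding is exhaustive whenever the adapter is at least
#' `(max_mismatch + 1) * kmer` long (pigeonhole); shorter features may miss
#' interior mismatched placements, which is why 5'-anchored primers are
#' handled by direct anchored evaluation in [trim_adapters_primers()].
#'
#' @param read_bases IUPAC base string.
#' @param adapter ACGT adapter string.
#' @param params A [trim_params()].
#' @return `list(start, end, mismatches)` in 1-based inclusive read
#'   coordinates, or `NULL` when no admissible placement exists.
#' @export
locate_adapter <- function(read_bases, adapter, params = trim_params()) {
  if (!nzchar(adapter)) stop("adapter must be non-empty")
  read_bases <- toupper(read_bases)
  adapter <- toupper(adapter)
  la <- nchar(adapter)
  lr <- nchar(read_bases)
  if (lr == 0L) return(NULL)
  k <- min(params$kmer, la)
  offsets <- integer(0)
  if (lr >= k) {
    read_kmers <- substring(read_bases, 1:(lr - k + 1L), k:lr)
    adapter_kmers <- substring(adapter, 1:(la - k + 1L), k:la)
    for (j in seq_along(adapter_kmers)) {
      hits <- which(read_kmers == adapter_kmers[j])
      if (length(hits)) offsets <- c(offsets, hits - j)  # 0-based offsets
    }
  }
  # 3'-terminal occurrences of the adapter prefix (up to the full adapter
  # ending exactly at the read end)
  max_terminal <- min(la, lr)
  if (max_terminal >= params$min_overlap) {
    offsets <- c(offsets, lr - seq(params$min_overlap, max_terminal))
  }
  offsets <- unique(offsets)
  offsets <- sort(offsets[offsets >= 0L & offsets < lr])
  best <- NULL
  for (o in offsets) {
    al <- align_at_offset(read_bases, adapter, o, la, lr, params$min_overlap)
    if (is.null(al)) next
    allowed <- ceiling(params$max_mismatch * al$aligned / la)
    if (al$mismatches > allowed) next
    if (is.null(best) || al$mismatches < best$mismatches) best <- al
  }
  if (is.null(best)) return(NULL)
  list(start = best$start, end = best$end, mismatches = best$mismatches)
}

# Features to search for a given read orientation: the read's own
# orientation sequence is primary; the opposite orientation appears
# read-through as its reverse complement at the 3' end.
features_for_orientation <- function(specs, orientation) {
  out <- list()
  for (sp in specs) {
    own <- if (orientation == "reverse") sp$reverse_seq else sp$forward_seq
    other <- if (orientation == "reverse") sp$forward_seq else sp$reverse_seq
    if (nzchar(own)) {
      out[[length(out) + 1L]] <- list(seq = own, type = sp$feature_type,
                                      anchored5 = sp$feature_type == "primer")
    }
    if (nzchar(other)) {
      out[[length(out) + 1L]] <- list(seq = revcomp(other), type = sp$feature_type,
                                      anchored5 = FALSE)
    }
  }
  out
}

# Direct evaluation of a 5'-anchored primer: full (or 3'-truncated)
# placements at offsets 0..2 only.
locate_anchored_primer <- function(read_bases, primer, params) {
  la <- nchar(primer)
  lr <- nchar(read_bases)
  best <- NULL
  for (o in 0:2) {
    if (o >= lr) break
    al <- align_at_offset(read_bases, primer, o, la, lr, params$min_overlap)
    if (is.null(al)) next
    allowed <- ceiling(params$max_mismatch * al$aligned / la)
    if (al$mismatches > allowed) next
    if (is.null(best) || al$mismatches < best$mismatches) best <- al
  }
  best
}

#' Trim adapters and primers from a read
#'
#' Features in the read's own orientation are searched directly; features of
#' the opposite orientation are searched as their reverse complement. A
#' primer placement anchored within the first 3 bases trims the 5' end up to
#' the match end; any adapter-like placement trims from the match start to
#' the 3' end. Qualities are trimmed in lockstep, and the search is applied
#' iteratively until no feature matches (at most 3 rounds).
#'
#' @param record A [seq_record()].
#' @param specs List of [adapter_spec()]s (empty list is a no-op).
#' @param params A [trim_params()].
#' @param orientation Pair role used to orient features (defaults to the
#'   record's own).
#' @return The trimmed [seq_record()].
#' @export
trim_adapters_primers <- function(record, specs, params = trim_params(),
                                  orientation = record$pair_role) {
  if (!length(specs)) return(record)
  feats <- features_for_orientation(specs, orientation)
  if (!length(feats)) return(record)
  for (round in 1:3) {
    changed <- FALSE
    for (f in feats) {
      n <- record_length(record)
      if (n == 0L) break
      if (f$anchored5) {
        hit <- locate_anchored_primer(record$bases, f$seq, params)
        if (!is.null(hit)) {
          keep <- seq.int(hit$end + 1L, length.out = n - hit$end)
          record <- subset_record(record, keep)
          changed <- TRUE
        }
      } else {
        hit <- locate_adapter(record$bases, f$seq, params)
        if (!is.null(hit)) {
          record <- subset_record(record, seq_len(hit$start - 1L))
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  record
}

#' Trim terminal N runs
#'
#' Removes leading and trailing runs of N (with their qualities); interior
#' Ns are untouched.
#'
#' @param record A [seq_record()].
#' @return The trimmed [seq_record()].
#' @export
trim_terminal_ns <- function(record) {
  b <- strsplit(record$bases, "")[[1]]
  keep <- which(b != "N")
  if (!length(keep)) return(subset_record(record, integer(0)))
  lo <- keep[1]
  hi <- keep[length(keep)]
  if (lo == 1L && hi == length(b)) return(record)
  subset_record(record, lo:hi)
}

#' Trim low-quality read ends
#'
#' From the 3' end, while the mean quality of the terminal window of size
#' `min(window, current length)` is below `q_trim`, the terminal base is
#' dropped; the same rule is applied from the 5' end, and the two passes
#' repeat until a fixed point (which makes the operation idempotent).
#'
#' @param record A [seq_record()].
#' @param q_trim Phred threshold (default 20).
#' @param window Window size (default 5).
#' @return The trimmed [seq_record()].
#' @export
trim_quality_ends <- function(record, q_trim = 20, window = 5L) {
  q <- record$quals
  lo <- 1L
  hi <- length(q)
  repeat {
    lo0 <- lo
    hi0 <- hi
    while (hi >= lo) {
      w <- min(window, hi - lo + 1L)
      if (mean(q[(hi - w + 1L):hi]) >= q_trim) break
      hi <- hi - 1L
    }
    while (hi >= lo) {
      w <- min(window, hi - lo + 1L)
      if (mean(q[lo:(lo + w - 1L)]) >= q_trim) break
      lo <- lo + 1L
    }
    if (lo == lo0 && hi == hi0) break
  }
  if (lo == 1L && hi == length(q)) return(record)
  if (hi < lo) return(subset_record(record, integer(0)))
  subset_record(record, lo:hi)
}

#' Full trimming cascade
#'
#' Applies adapter/primer trimming, terminal-N trimming and quality-end
#' trimming, iterating the three steps until the read stops shrinking; the
#' composite is therefore idempotent.
#'
#' @inheritParams trim_adapters_primers
#' @return The trimmed [seq_record()].
#' @export
trim_cascade <- function(record, specs = list(), params = trim_params(),
                         orientation = record$pair_role) {
  repeat {
    n0 <- record_length(record)
    record <- trim_adapters_primers(record, specs, params, orientation)
    record <- trim_terminal_ns(record)
    record <- trim_quality_ends(record, params$q_trim, params$window)
    if (record_length(record) == n0) break
  }
  record
}
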