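# IUPAC nucleotide alphabet, upper-case canonical.
IUPAC_ALPHABET <- c("A", "C", "G", "T", "U", "N",
                    "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

# base-set -> ambiguity code, keyed by the sorted concatenation of A/C/G/T
IUPAC_CODE_MAP <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AG" = "R", "CT" = "Y", "CG" = "S", "AT" = "W",
  "GT" = "K", "AC" = "M",
  "CGT" = "B", "AGT" = "D", "ACT" = "H", "ACG" = "V",
  "ACGT" = "N"
)

iupac_code <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- IUPAC_CODE_MAP[[key]]
  if (is.null(code)) stop("no IUPAC code for base set {", key, "}")
  code
}

#' Construct a sequence record
#'
#' The unit record of the toolkit: one read with its identifier, base string
#' over the IUPAC nucleotide alphabet, per-base Phred quality integers and a
#' pair role.
#'
#' @param read_id Character scalar identifier.
#' @param bases Base string; lower-case input is upper-cased.
#' @param quals Integer vector of Phred qualities, one per base, each in
#'   `[0, 93]` (the Sanger-encodable range).
#' @param pair_role One of `"single"`, `"forward"`, `"reverse"`.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(read_id, bases, quals,
                       pair_role = c("single", "forward", "reverse")) {
  pair_role <- match.arg(pair_role)
  rec <- structure(
    list(read_id = as.character(read_id)[1],
         bases = toupper(as.character(bases)[1]),
         quals = as.integer(quals),
         pair_role = pair_role),
    class = "seq_record"
  )
  validate_seq_record(rec)
  rec
}

validate_seq_record <- function(rec) {
  if (nchar(rec$bases) != length(rec$quals)) {
    stop("record '", rec$read_id, "': ", nchar(rec$bases), " bases but ",
         length(rec$quals), " qualities")
  }
  if (length(rec$quals) && (anyNA(rec$quals) ||
                            min(rec$quals) < 0L || max(rec$quals) > 93L)) {
    stop("record '", rec$read_id, "': qualities outside [0, 93]")
  }
  if (nchar(rec$bases) && !grepl("^[ACGTUNRYSWKMBDHV]*$", rec$bases)) {
    stop("record '", rec$read_id, "': non-IUPAC characters in bases")
  }
  invisible(rec)
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%s), %d bp, mean Q %.1f\n",
              x$read_id, x$pair_role, nchar(x$bases),
              if (length(x$quals)) mean(x$quals) else NA_real_))
  invisible(x)
}

#' Construct a chromatogram record
#'
#' A [seq_record()] extended with four-channel trace signals, the channel
#' order of the trace arrays, and per-base peak positions.
#'
#' @inheritParams seq_record
#' @param traces List of four equal-length non-negative integer vectors, one
#'   per dye channel, in the order given by `channel_order`.
#' @param channel_order Permutation string of `"ACGT"` mapping trace array
#'   index to base (e.g. `"GATC"` for a typical ABIF `FWO_` field).
#' @param peak_index Integer vector, one 1-based index into the trace arrays
#'   per called base; strictly increasing.
#' @return An object of class `chromatogram_record` (also a `seq_record`).
#' @export
chromatogram_record <- function(read_id, bases, quals, traces, channel_order,
                                peak_index, pair_role = "single") {
  rec <- seq_record(read_id, bases, quals, pair_role)
  rec$traces <- lapply(traces, as.integer)
  rec$channel_order <- toupper(channel_order)
  rec$peak_index <- as.integer(peak_index)
  class(rec) <- c("chromatogram_record", "seq_record")
  validate_chromatogram_record(rec)
  rec
}

validate_chromatogram_record <- function(rec) {
  if (length(rec$traces) != 4L) stop("chromatogram needs exactly 4 trace arrays")
  len <- unique(vapply(rec$traces, length, integer(1)))
  if (length(len) != 1L) stop("trace arrays differ in length")
  if (!identical(sort(strsplit(rec$channel_order, "")[[1]]),
                 c("A", "C", "G", "T"))) {
    stop("channel_order must be a permutation of ACGT, got '",
         rec$channel_order, "'")
  }
  if (length(rec$peak_index) != nchar(rec$bases)) {
    stop("peak_index length != number of bases")
  }
  if (length(rec$peak_index)) {
    if (min(rec$peak_index) < 1L || max(rec$peak_index) > len) {
      stop("peak_index outside trace arrays")
    }
    if (is.unsorted(rec$peak_index, strictly = TRUE)) {
      stop("peak_index not strictly increasing")
    }
  }
  invisible(rec)
}

#' Construct a flowgram (SFF) record
#'
#' A [seq_record()] extended with flow values, flow characters and the four
#' vendor clip coordinates of the SFF standard (1-based, 0 = absent).
#'
#' @inheritParams seq_record
#' @param flow_values Non-negative integer vector of flow intensities.
#' @param flow_chars Character string of nucleotide flowed at each flow; same
#'   length as `flow_values`.
#' @param clip_qual_left,clip_qual_right,clip_adapter_left,clip_adapter_right
#'   Vendor clip points per the SFF standard.
#' @return An object of class `flow_record` (also a `seq_record`).
#' @export
flow_record <- function(read_id, bases, quals, flow_values, flow_chars,
                        clip_qual_left = 0L, clip_qual_right = 0L,
                        clip_adapter_left = 0L, clip_adapter_right = 0L,
                        pair_role = "single") {
  rec <- seq_record(read_id, bases, quals, pair_role)
  rec$flow_values <- as.integer(flow_values)
  rec$flow_chars <- as.character(flow_chars)[1]
  rec$clip_qual_left <- as.integer(clip_qual_left)
  rec$clip_qual_right <- as.integer(clip_qual_right)
  rec$clip_adapter_left <- as.integer(clip_adapter_left)
  rec$clip_adapter_right <- as.integer(clip_adapter_right)
  class(rec) <- c("flow_record", "seq_record")
  if (length(rec$flow_values) != nchar(rec$flow_chars)) {
    stop("flow_values and flow_chars differ in length")
  }
  n <- nchar(rec$bases)
  clips <- c(rec$clip_qual_left, rec$clip_qual_right,
             rec$clip_adapter_left, rec$clip_adapter_right)
  if (any(clips < 0L) || any(clips[clips != 0L] > n)) {
    stop("record '", rec$read_id, "': clip coordinates outside [1, ", n, "]")
  }
  rec
}

#' Reverse-complement a nucleotide string
#'
#' Handles the full IUPAC alphabet (ambiguity codes map to the complement of
#' their base set; U complements to A).
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTUNRYSWKMBDHVacgtunryswkmbdhv",
                 "TGCAANYRSWMKVHDBtgcaanyrswmkvhdb", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Subset a record to base positions idx (logical or integer), keeping
# bases and qualities in lockstep. Trace/flow side data are dropped because
# they no longer align after trimming.
subset_record <- function(rec, idx) {
  b <- strsplit(rec$bases, "")[[1]][idx]
  seq_record(rec$read_id, paste(b, collapse = ""), rec$quals[idx],
             rec$pair_role)
}

record_length <- function(rec) nchar(rec$bases)
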