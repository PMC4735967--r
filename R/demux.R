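#' Build a barcode (MID) table
#'
#' @param sample_id Character vector of sample identifiers.
#' @param mid Character vector of barcode sequences over ACGT, same length.
#' @param max_mismatch Default mismatch tolerance carried with the table.
#' @return A `barcode_table` data frame.
#' @details All barcodes must be distinct. For barcodes of equal length the
#'   pairwise Hamming distance should exceed `2 * max_mismatch`; violations
#'   yield a warning at load time because reads between two close barcodes
#'   can then only be resolved as unassigned.
#' @export
barcode_table <- function(sample_id, mid, max_mismatch = 0L) {
  sample_id <- as.character(sample_id)
  mid <- toupper(as.character(mid))
  if (!length(mid)) stop("demultiplexing requested without barcodes")
  if (length(sample_id) != length(mid)) {
    stop("sample_id and mid differ in length")
  }
  if (any(!nzchar(mid)) || any(!grepl("^[ACGT]+$", mid))) {
    stop("barcodes must be non-empty ACGT strings")
  }
  if (anyDuplicated(mid)) stop("duplicate barcode sequences in table")
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in barcode table")
  for (i in seq_along(mid)) {
    for (j in seq_len(i - 1L)) {
      if (nchar(mid[i]) == nchar(mid[j]) &&
          hamming(mid[i], mid[j]) <= 2L * max_mismatch) {
        warning("barcodes '", mid[i], "' and '", mid[j],
                "' are within 2*max_mismatch of each other; ",
                "reads between them will be unassigned")
      }
    }
  }
  structure(data.frame(sample_id = sample_id, mid = mid,
                       stringsAsFactors = FALSE),
            max_mismatch = as.integer(max_mismatch),
            class = c("barcode_table", "data.frame"))
}

hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

#' Assign a read to a sample by its 5' barcode
#'
#' Computes the Hamming distance between each barcode and the read prefix of
#' equal length (N in the read counts as a mismatch). Longer barcodes take
#' priority: lengths are tried longest first, and the first length with any
#' candidate within `max_mismatch` decides. A unique minimum-distance
#' candidate wins; a tie (or no candidate at any length) leaves the read
#' unassigned. On assignment the barcode prefix and its qualities are
#' removed.
#'
#' @param record A [seq_record()].
#' @param table A [barcode_table()].
#' @param max_mismatch Maximum Hamming distance (default: the table's).
#' @return `list(sample_id = <id or NA>, record = <possibly trimmed record>)`.
#' @export
assign_barcode <- function(record, table,
                           max_mismatch = attr(table, "max_mismatch")) {
  if (is.null(max_mismatch)) max_mismatch <- 0L
  n <- record_length(record)
  for (len in sort(unique(nchar(table$mid)), decreasing = TRUE)) {
    if (len > n) next  # read shorter than these barcodes: cannot match
    rows <- which(nchar(table$mid) == len)
    prefix <- substr(record$bases, 1L, len)
    d <- vapply(table$mid[rows], hamming, integer(1), a = prefix,
                USE.NAMES = FALSE)
    cand <- rows[d <= max_mismatch]
    if (!length(cand)) next
    dmin <- min(d[d <= max_mismatch])
    winners <- rows[d == dmin]
    if (length(winners) != 1L) {
      return(list(sample_id = NA_character_, record = record))
    }
    trimmed <- subset_record(record, seq.int(len + 1L, length.out = n - len))
    return(list(sample_id = table$sample_id[winners], record = trimmed))
  }
  list(sample_id = NA_character_, record = record)
}

#' Demultiplex a read stream by 5' barcodes
#'
#' Partitions reads into one bin per sample plus an `"unassigned"` bin; every
#' read lands in exactly one bin. For paired input the barcode is read from
#' the forward read only and the mate follows its assignment. When `out_dir`
#' is given, one FASTQ per sample is written (two, `_R1`/`_R2`, for pairs)
#' plus the unassigned bin.
#'
#' @param reads List of [seq_record()]s, or for paired-end input a
#'   `list(fwd = <records>, rev = <records>)` with equal lengths.
#' @param table A [barcode_table()].
#' @param out_dir Optional output directory for per-sample FASTQ files.
#' @param max_mismatch Maximum Hamming distance (default: the table's).
#' @return Named integer vector of per-bin counts (samples then
#'   `unassigned`), with the per-sample record bins in attribute `"bins"`.
#' @export
demultiplex <- function(reads, table, out_dir = NULL,
                        max_mismatch = attr(table, "max_mismatch")) {
  if (!inherits(table, "barcode_table") || !nrow(table)) {
    stop("demultiplexing requested without barcodes")
  }
  if (is.null(max_mismatch)) max_mismatch <- 0L
  paired <- is.list(reads) && !is.null(names(reads)) &&
    all(c("fwd", "rev") %in% names(reads))
  if (paired && length(reads$fwd) != length(reads$rev)) {
    stop("paired input with unequal mate counts")
  }
  fwd <- if (paired) reads$fwd else reads
  bin_names <- c(table$sample_id, "unassigned")
  bins <- stats::setNames(rep(list(list()), length(bin_names)), bin_names)
  if (paired) {
    bins_rev <- bins
  }
  for (i in seq_along(fwd)) {
    hit <- assign_barcode(fwd[[i]], table, max_mismatch)
    bin <- if (is.na(hit$sample_id)) "unassigned" else hit$sample_id
    bins[[bin]][[length(bins[[bin]]) + 1L]] <- hit$record
    if (paired) {
      bins_rev[[bin]][[length(bins_rev[[bin]]) + 1L]] <- reads$rev[[i]]
    }
  }
  counts <- vapply(bins, length, integer(1))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (bin in bin_names) {
      if (paired) {
        write_fastq_sanger(bins[[bin]],
                           file.path(out_dir, paste0(bin, "_R1.fastq")))
        write_fastq_sanger(bins_rev[[bin]],
                           file.path(out_dir, paste0(bin, "_R2.fastq")))
      } else {
        write_fastq_sanger(bins[[bin]],
                           file.path(out_dir, paste0(bin, ".fastq")))
      }
    }
  }
  attr(counts, "bins") <- bins
  if (paired) attr(counts, "bins_rev") <- bins_rev
  counts
}
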