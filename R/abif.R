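#' Read a Sanger chromatogram (AB1/ABIF or SCF v3)
#'
#' For ABIF files, base calls come from tag `PBAS.1`, per-base qualities
#' from `PCON.1`, peak positions from `PLOC.1`, the channel order from
#' `FWO_.1` and the four processed trace arrays from `DATA.9`-`DATA.12`
#' (raw traces `DATA.1`-`DATA.8` are ignored). For SCF, only version >= 3.00
#' is supported; bases, qualities and peak offsets come from the bases block
#' and the traces from the delta-encoded samples block. Qualities are
#' clamped into `[0, 93]`.
#'
#' @param path Path to the trace file; one trace file holds one read.
#' @param format `"ab1"`, `"scf"`, or `NULL` to detect via [detect_format()].
#' @return A [chromatogram_record()].
#' @export
read_chromatogram <- function(path, format = NULL) {
  if (is.null(format)) format <- detect_format(path)
  switch(format,
         ab1 = read_abif_chromatogram(path),
         scf = read_scf_chromatogram(path),
         stop("'", path, "' is not a chromatogram format (detected '",
              format, "')"))
}

parse_abif_entry <- function(r, at) {
  list(name = rchr(r, at, 4L, "directory entry name"),
       number = ru32(r, at + 4L),
       elemtype = ru16(r, at + 8L),
       elemsize = ru16(r, at + 10L),
       numelements = ru32(r, at + 12L),
       datasize = ru32(r, at + 16L),
       dataoffset = ru32(r, at + 20L),
       inline = r[(at + 20L):(at + 23L)])
}

abif_entry_raw <- function(r, e) {
  if (e$datasize <= 4) return(e$inline[seq_len(e$datasize)])
  check_span(r, e$dataoffset + 1L, e$datasize,
             paste0("data of tag ", e$name, ".", e$number))
  r[(e$dataoffset + 1L):(e$dataoffset + e$datasize)]
}

read_abif_chromatogram <- function(path) {
  r <- read_file_raw(path)
  if (length(r) < 34L || !identical(r[1:4], charToRaw("ABIF"))) {
    stop("'", path, "': bad magic, not an ABIF file")
  }
  head_entry <- parse_abif_entry(r, 7L)
  ndir <- head_entry$numelements
  diroff <- head_entry$dataoffset + 1L
  entries <- list()
  for (k in seq_len(ndir)) {
    e <- parse_abif_entry(r, diroff + 28L * (k - 1L))
    entries[[paste0(e$name, ".", e$number)]] <- e
  }
  need <- function(tag) {
    e <- entries[[tag]]
    if (is.null(e)) {
      stop("'", path, "': missing mandatory ABIF tag ", tag)
    }
    e
  }
  bases <- toupper(rawToChar(abif_entry_raw(r, need("PBAS.1"))))
  quals <- as.integer(abif_entry_raw(r, need("PCON.1")))
  quals <- pmin(pmax(quals, 0L), 93L)
  ploc_raw <- abif_entry_raw(r, need("PLOC.1"))
  ploc <- readBin(ploc_raw, "integer", n = length(ploc_raw) %/% 2L,
                  size = 2L, endian = "big", signed = FALSE)
  fwo <- toupper(rawToChar(abif_entry_raw(r, need("FWO_.1"))))
  traces <- lapply(9:12, function(num) {
    raw <- abif_entry_raw(r, need(paste0("DATA.", num)))
    readBin(raw, "integer", n = length(raw) %/% 2L,
            size = 2L, endian = "big", signed = FALSE)
  })
  chromatogram_record(
    read_id = sub("\\.[^.]*$", "", basename(path)),
    bases = bases, quals = quals,
    traces = traces, channel_order = fwo,
    peak_index = ploc + 1L  # PLOC stores 0-based sample indices
  )
}
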