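#' Read an SFF v1 flowgram file
#'
#' Parses the big-endian Standard Flowgram Format used by 454 and Ion
#' Torrent instruments. An index section, if present, is skipped. Vendor
#' clip coordinates are preserved verbatim on each record; applying them is
#' the pipeline's conversion step, not the reader's.
#'
#' @param path SFF file path.
#' @return List of [flow_record()]s in file order (possibly empty).
#' @export
read_sff <- function(path) {
  r <- read_file_raw(path)
  if (length(r) < 31L || !identical(r[1:4], as.raw(c(0x2e, 0x73, 0x66, 0x66)))) {
    stop("'", path, "': bad magic, not an SFF file")
  }
  version <- ru32(r, 5L)
  if (version != 1) {
    stop("'", path, "': unsupported SFF version ", version)
  }
  index_offset <- ru32(r, 9L) * 4294967296 + ru32(r, 13L)
  index_length <- ru32(r, 17L)
  nreads <- ru32(r, 21L)
  header_length <- ru16(r, 25L)
  key_length <- ru16(r, 27L)
  nflows <- ru16(r, 29L)
  fmt <- ru8(r, 31L)
  if (fmt != 1L) stop("'", path, "': unsupported flowgram format code ", fmt)
  flow_chars <- rchr(r, 32L, nflows, "flow characters")
  pos <- header_length + 1
  out <- vector("list", nreads)
  for (i in seq_len(nreads)) {
    if (index_offset > 0 && pos == index_offset + 1) {
      pos <- pos + index_length
      pos <- pos + (8 - (pos - 1) %% 8) %% 8
    }
    rhl <- ru16(r, pos, what = paste0("read ", i, " header"))
    nml <- ru16(r, pos + 2L)
    nb <- ru32(r, pos + 4L)
    cql <- ru16(r, pos + 8L)
    cqr <- ru16(r, pos + 10L)
    cal <- ru16(r, pos + 12L)
    car <- ru16(r, pos + 14L)
    expected_rhl <- 16L + nml
    expected_rhl <- expected_rhl + (8L - expected_rhl %% 8L) %% 8L
    if (rhl != expected_rhl) {
      stop("'", path, "': read ", i, ": header length ", rhl,
           " does not match name length ", nml)
    }
    name <- rchr(r, pos + 16L, nml, paste0("read ", i, " name"))
    pos <- pos + rhl
    flows <- ru16(r, pos, nflows, paste0("read ", i, " flowgram"))
    pos <- pos + 2L * nflows
    pos <- pos + nb  # flow_index_per_base: parsed past, not retained
    bases <- toupper(rchr(r, pos, nb, paste0("read ", i, " bases")))
    pos <- pos + nb
    quals <- ru8(r, pos, nb, paste0("read ", i, " qualities"))
    pos <- pos + nb
    datalen <- 2L * nflows + 3L * nb
    pos <- pos + (8L - datalen %% 8L) %% 8L
    out[[i]] <- flow_record(
      read_id = name, bases = bases, quals = pmin(pmax(quals, 0L), 93L),
      flow_values = flows, flow_chars = flow_chars,
      clip_qual_left = cql, clip_qual_right = cqr,
      clip_adapter_left = cal, clip_adapter_right = car)
  }
  out
}

# Apply SFF vendor clips to a flow record, per the SFF standard semantics:
# first usable base = max(1, clip_qual_left, clip_adapter_left), last usable
# base = min over the non-zero right clips (whole read when both are 0).
apply_sff_clips <- function(rec) {
  n <- record_length(rec)
  left <- max(1L, rec$clip_qual_left, rec$clip_adapter_left)
  rights <- c(rec$clip_qual_right, rec$clip_adapter_right)
  rights <- rights[rights != 0L]
  right <- if (length(rights)) min(rights) else n
  if (left > right) return(subset_record(rec, integer(0)))
  subset_record(rec, left:right)
}
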