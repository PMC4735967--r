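# SCF v3 reader (Staden layout): 128-byte header, then per-channel
# double-delta-encoded sample arrays (A, C, G, T), then the bases block
# (peak offsets u32, four probability arrays, base characters, spare).

scf_delta_decode <- function(x, bits) {
  m <- 2^bits
  x <- cumsum(as.numeric(x)) %% m
  as.integer(cumsum(x) %% m)
}

scf_delta_encode <- function(x, bits) {
  m <- 2^bits
  x <- as.numeric(x)
  for (k in 1:2) x <- c(x[1], diff(x)) %% m
  as.integer(x)
}

read_scf_chromatogram <- function(path) {
  r <- read_file_raw(path)
  if (length(r) < 128L || !identical(r[1:4], charToRaw(".scf"))) {
    stop("'", path, "': bad magic, not an SCF file")
  }
  samples <- ru32(r, 5L)
  samples_offset <- ru32(r, 9L)
  nbases <- ru32(r, 13L)
  bases_offset <- ru32(r, 25L)
  version <- rchr(r, 37L, 4L)
  sample_size <- ru32(r, 41L)
  vnum <- suppressWarnings(as.numeric(version))
  if (is.na(vnum) || vnum < 3) {
    stop("'", path, "': SCF version '", version,
         "' unsupported (only version >= 3.00 is read)")
  }
  if (!sample_size %in% c(1, 2)) {
    stop("'", path, "': invalid SCF sample_size ", sample_size)
  }
  traces <- vector("list", 4L)  # file order: A, C, G, T
  for (k in 1:4) {
    at <- samples_offset + 1L + (k - 1L) * samples * sample_size
    v <- if (sample_size == 2) {
      ru16(r, at, samples, what = "samples block")
    } else {
      ru8(r, at, samples, what = "samples block")
    }
    traces[[k]] <- scf_delta_decode(v, 8L * sample_size)
  }
  bo <- bases_offset + 1L
  peaks <- if (nbases) ru32(r, bo, nbases, what = "peak offsets") else numeric(0)
  prob <- lapply(0:3, function(k) {
    if (nbases) ru8(r, bo + 4L * nbases + k * nbases, nbases, "probabilities")
    else integer(0)
  })
  bases <- if (nbases) {
    toupper(rchr(r, bo + 8L * nbases, nbases, "base characters"))
  } else ""
  bvec <- strsplit(bases, "")[[1]]
  chan <- match(bvec, c("A", "C", "G", "T"))
  quals <- integer(nbases)
  for (i in seq_len(nbases)) {
    quals[i] <- if (!is.na(chan[i])) {
      prob[[chan[i]]][i]
    } else {
      max(prob[[1]][i], prob[[2]][i], prob[[3]][i], prob[[4]][i])
    }
  }
  quals <- pmin(pmax(quals, 0L), 93L)
  chromatogram_record(
    read_id = sub("\\.[^.]*$", "", basename(path)),
    bases = bases, quals = quals,
    traces = traces, channel_order = "ACGT",
    peak_index = as.integer(peaks) + 1L  # stored 0-based
  )
}
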