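# Synthetic data with planted, machine-readable ground truth. The format
# writers here build raw byte vectors directly and share no parsing code
# with the readers, so round-trip tests exercise two independent codings of
# each specification.

random_dna <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

mutate_bases <- function(s, k) {
  if (k <= 0L) return(s)
  chars <- strsplit(s, "")[[1]]
  pos <- sample(seq_along(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate synthetic reads with ground truth
#'
#' Read lengths are uniform over `[length_model$min, length_model$max]`.
#' The quality model emulates the 3'-decaying accuracy of short-read
#' sequencing: per-read mean quality falls linearly from
#' `quality_model$start` at the 5' end to `quality_model$end` at the 3' end
#' with Gaussian noise `quality_model$sd`, clamped into `[2, 40]`.
#'
#' @param n Number of reads.
#' @param length_model `list(min =, max =)` read length bounds.
#' @param quality_model `list(start =, end =, sd =)` Phred decay model.
#' @param seed Mandatory RNG seed; a given seed reproduces the output.
#' @param id_prefix Read identifier prefix.
#' @return `list(reads = <records>, truth = <data.frame>)`; `truth` has one
#'   row per read (`read_id`, `insert`, `length`).
#' @export
generate_reads <- function(n,
                           length_model = list(min = 80L, max = 120L),
                           quality_model = list(start = 35, end = 25, sd = 3),
                           seed, id_prefix = "read") {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  reads <- vector("list", n)
  truth <- data.frame(read_id = character(n), insert = character(n),
                      length = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    len <- sample(length_model$min:length_model$max, 1)
    bases <- random_dna(len)
    t <- if (len > 1) (seq_len(len) - 1) / (len - 1) else 0
    mu <- quality_model$start + (quality_model$end - quality_model$start) * t
    q <- as.integer(pmin(pmax(round(mu + stats::rnorm(len, 0,
                                                      quality_model$sd)),
                              2), 40))
    id <- sprintf("%s_%05d", id_prefix, i)
    reads[[i]] <- seq_record(id, bases, q)
    truth$read_id[i] <- id
    truth$insert[i] <- bases
    truth$length[i] <- len
  }
  list(reads = reads, truth = truth)
}

#' Plant barcodes, primers and adapters into synthetic reads
#'
#' Features are added outside-in: `barcode + primer + insert + adapter`.
#' Primer/adapter copies carry the per-read substitution counts drawn from
#' `feature_mismatches`; planted feature bases get quality 30. When
#' `avoid_spurious` is `TRUE` (the default) inserts whose 3' end already
#' resembles the adapter prefix (or whose 5' end resembles the primer)
#' under the matching rule are regenerated, so that the recorded feature
#' positions are the only admissible matches and the ground truth is
#' unambiguous.
#'
#' @param sim A `list(reads, truth)` from [generate_reads()].
#' @param barcodes Optional [barcode_table()]; with `assignments`, a
#'   character vector of `sample_id` (or `NA` for barcode-free) per read.
#' @param assignments See `barcodes`.
#' @param primer,adapter Optional ACGT strings planted at the 5'/3' ends.
#' @param feature_mismatches Integer vector of allowed substitution counts
#'   sampled per read and per feature (default `0`).
#' @param params [trim_params()] used only for the spurious-match screen.
#' @param avoid_spurious Regenerate inserts with accidental feature-like
#'   ends (see above).
#' @param seed Mandatory RNG seed.
#' @return `list(reads, truth)` with truth columns `sample_id`, `barcode`,
#'   `primer_mm`, `adapter_mm` added.
#' @export
plant_features <- function(sim, barcodes = NULL, assignments = NULL,
                           primer = NULL, adapter = NULL,
                           feature_mismatches = 0L,
                           params = trim_params(), avoid_spurious = TRUE,
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  reads <- sim$reads
  truth <- sim$truth
  n <- length(reads)
  truth$sample_id <- NA_character_
  truth$barcode <- NA_character_
  truth$primer_mm <- NA_integer_
  truth$adapter_mm <- NA_integer_
  if (!is.null(barcodes) && is.null(assignments)) {
    stop("barcodes given without per-read assignments")
  }
  for (i in seq_len(n)) {
    rec <- reads[[i]]
    if (avoid_spurious &&
        (!is.null(primer) || !is.null(adapter) ||
         (!is.null(barcodes) && is.na(assignments[i])))) {
      # a barcode-free read whose bare 5' end would sit at the front of the
      # final construct must not start with a barcode either, or the
      # planted truth would be ambiguous
      mids <- if (!is.null(barcodes) && is.na(assignments[i]) &&
                  is.null(primer)) barcodes$mid else character(0)
      tries <- 0L
      while ((has_spurious_feature_match(rec$bases, primer, adapter, params) ||
              any(vapply(mids, startsWith, logical(1), x = rec$bases))) &&
             tries < 50L) {
        rec$bases <- random_dna(nchar(rec$bases))
        tries <- tries + 1L
      }
      truth$insert[i] <- rec$bases
      reads[[i]] <- rec
    }
    bases <- rec$bases
    quals <- rec$quals
    if (!is.null(adapter)) {
      mm <- sample(rep(feature_mismatches, 2L), 1)
      planted <- mutate_bases(adapter, mm)
      bases <- paste0(bases, planted)
      quals <- c(quals, rep(30L, nchar(planted)))
      truth$adapter_mm[i] <- mm
    }
    if (!is.null(primer)) {
      mm <- sample(rep(feature_mismatches, 2L), 1)
      planted <- mutate_bases(primer, mm)
      bases <- paste0(planted, bases)
      quals <- c(rep(30L, nchar(planted)), quals)
      truth$primer_mm[i] <- mm
    }
    if (!is.null(barcodes)) {
      sid <- assignments[i]
      if (!is.na(sid)) {
        mid <- barcodes$mid[match(sid, barcodes$sample_id)]
        bases <- paste0(mid, bases)
        quals <- c(rep(30L, nchar(mid)), quals)
        truth$sample_id[i] <- sid
        truth$barcode[i] <- mid
      }
    }
    reads[[i]] <- seq_record(rec$read_id, bases, quals, rec$pair_role)
  }
  list(reads = reads, truth = truth)
}

# TRUE when the bare insert already contains an admissible primer or
# adapter placement under the ungapped matching rule (checked by direct
# enumeration of all offsets, independent of the seeded matcher).
has_spurious_feature_match <- function(bases, primer, adapter, params) {
  check_one <- function(feature) {
    if (is.null(feature)) return(FALSE)
    la <- nchar(feature)
    lr <- nchar(bases)
    for (o in 0:(lr - 1L)) {
      aligned <- min(la, lr - o)
      if (aligned < la && aligned < params$min_overlap) next
      mm <- count_mismatches(substr(bases, o + 1L, o + aligned),
                             substr(feature, 1L, aligned))
      if (mm <= ceiling(params$max_mismatch * aligned / la)) return(TRUE)
    }
    FALSE
  }
  check_one(adapter) || check_one(primer) ||
    (!is.null(primer) && check_one(revcomp(primer))) ||
    (!is.null(adapter) && check_one(revcomp(adapter)))
}

# ---- synthetic trace writers -------------------------------------------

# Gaussian peak traces: peaks evenly spaced every `spacing` samples, primary
# height 1000; `secondary` plants extra channel peaks for ambiguity tests,
# as a list of list(pos = <base index>, bases = <chr>, heights = <int>).
synth_traces <- function(bases, spacing = 12L, height = 1000,
                         secondary = NULL, channel_order = "ACGT") {
  bvec <- strsplit(toupper(bases), "")[[1]]
  n <- length(bvec)
  centers <- spacing * seq_len(n) - spacing %/% 2L
  len <- spacing * n + spacing
  chans <- strsplit(channel_order, "")[[1]]
  traces <- stats::setNames(rep(list(numeric(len)), 4L), chans)
  x <- seq_len(len)
  add_peak <- function(tr, center, h) {
    tr + h * exp(-((x - center)^2) / (2 * 2.5^2))
  }
  sec_at <- integer(0)
  if (!is.null(secondary)) {
    sec_at <- vapply(secondary, function(s) as.integer(s$pos), integer(1))
  }
  for (i in seq_len(n)) {
    si <- match(i, sec_at)
    if (!is.na(si)) {
      s <- secondary[[si]]
      sb <- strsplit(toupper(paste(s$bases, collapse = "")), "")[[1]]
      for (k in seq_along(sb)) {
        traces[[sb[k]]] <- add_peak(traces[[sb[k]]], centers[i], s$heights[k])
      }
    } else if (bvec[i] %in% chans) {
      traces[[bvec[i]]] <- add_peak(traces[[bvec[i]]], centers[i], height)
    }
  }
  list(traces = lapply(traces, function(tr) as.integer(round(tr))),
       peak_index = centers, channel_order = channel_order)
}

#' Write a synthetic chromatogram file
#'
#' Builds a minimal but specification-conformant AB1 (ABIF) or SCF v3 file
#' for one record, with Gaussian-peak traces synthesised from the base
#' calls. The writer constructs the byte layout directly and shares no code
#' with [read_chromatogram()].
#'
#' @param record A [seq_record()] (bases + qualities).
#' @param format `"ab1"` or `"scf"`.
#' @param path Output path.
#' @param channel_order Channel order written to the file (AB1 `FWO_` tag;
#'   SCF always stores A,C,G,T blocks).
#' @param secondary Optional planted secondary peaks for ambiguity tests;
#'   see the fixtures module internals.
#' @return `path`, invisibly, with the synthesised traces and peak indices
#'   in attributes `"traces"`, `"peak_index"` and `"channel_order"` (the
#'   planted per-channel truth, recorded independently of any reader).
#' @export
write_synthetic_trace <- function(record, format = c("ab1", "scf"), path,
                                  channel_order = if (format == "ab1") "GATC"
                                                  else "ACGT",
                                  secondary = NULL) {
  format <- match.arg(format)
  if (format == "scf") channel_order <- "ACGT"
  ts <- synth_traces(record$bases, secondary = secondary,
                     channel_order = channel_order)
  if (format == "ab1") {
    write_abif_fixture(record, ts, path)
  } else {
    write_scf_fixture(record, ts, path)
  }
  attr(path, "traces") <- ts$traces
  attr(path, "peak_index") <- ts$peak_index
  attr(path, "channel_order") <- ts$channel_order
  invisible(path)
}

abif_dir_entry <- function(name, number, elemtype, elemsize, numelements,
                           datasize, dataoffset, inline = NULL) {
  stopifnot(nchar(name) == 4L)
  off_bytes <- if (!is.null(inline)) {
    c(inline, as.raw(integer(4L - length(inline))))
  } else {
    w_u32(dataoffset)
  }
  c(w_chr(name), w_u32(number), w_u16(elemtype), w_u16(elemsize),
    w_u32(numelements), w_u32(datasize), off_bytes, w_u32(0))
}

write_abif_fixture <- function(record, ts, path) {
  n <- record_length(record)
  tracelen <- length(ts$traces[[1]])
  # data blocks in write order; traces stored per FWO_ channel order
  chans <- strsplit(ts$channel_order, "")[[1]]
  blocks <- list(
    PBAS = w_chr(record$bases),
    PCON = w_u8(record$quals),
    PLOC = w_u16(ts$peak_index - 1L),  # 0-based sample indices
    FWO_ = w_chr(ts$channel_order),
    DATA9 = w_u16(ts$traces[[chans[1]]]),
    DATA10 = w_u16(ts$traces[[chans[2]]]),
    DATA11 = w_u16(ts$traces[[chans[3]]]),
    DATA12 = w_u16(ts$traces[[chans[4]]]))
  header_len <- 128L
  offsets <- header_len + cumsum(c(0L, vapply(blocks, length,
                                              integer(1))[-length(blocks)]))
  names(offsets) <- names(blocks)
  dir_offset <- header_len + sum(vapply(blocks, length, integer(1)))
  mk <- function(name, number, elemtype, elemsize, numelements, block,
                 offset) {
    datasize <- length(block)
    if (datasize <= 4L) {
      abif_dir_entry(name, number, elemtype, elemsize, numelements,
                     datasize, 0, inline = block)
    } else {
      abif_dir_entry(name, number, elemtype, elemsize, numelements,
                     datasize, offset)
    }
  }
  entries <- c(
    mk("PBAS", 1, 2L, 1L, n, blocks$PBAS, offsets["PBAS"]),
    mk("PCON", 1, 1L, 1L, n, blocks$PCON, offsets["PCON"]),
    mk("PLOC", 1, 4L, 2L, n, blocks$PLOC, offsets["PLOC"]),
    mk("FWO_", 1, 2L, 1L, 4L, blocks$FWO_, offsets["FWO_"]),
    mk("DATA", 9, 4L, 2L, tracelen, blocks$DATA9, offsets["DATA9"]),
    mk("DATA", 10, 4L, 2L, tracelen, blocks$DATA10, offsets["DATA10"]),
    mk("DATA", 11, 4L, 2L, tracelen, blocks$DATA11, offsets["DATA11"]),
    mk("DATA", 12, 4L, 2L, tracelen, blocks$DATA12, offsets["DATA12"]))
  header <- c(w_chr("ABIF"), w_u16(101),
              abif_dir_entry("tdir", 1, 1023L, 28L, 8L, 8L * 28L,
                             dir_offset))
  header <- c(header, as.raw(integer(header_len - length(header))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, do.call(c, unname(blocks)), entries), con)
  invisible(path)
}

write_scf_fixture <- function(record, ts, path) {
  n <- record_length(record)
  tracelen <- length(ts$traces[[1]])
  samples_offset <- 128L
  samples_bytes <- 4L * 2L * tracelen
  bases_offset <- samples_offset + samples_bytes
  bvec <- strsplit(record$bases, "")[[1]]
  prob <- matrix(0L, nrow = 4L, ncol = n)  # rows A, C, G, T
  for (i in seq_len(n)) {
    ch <- match(bvec[i], c("A", "C", "G", "T"))
    if (!is.na(ch)) {
      prob[ch, i] <- record$quals[i]
    } else {
      prob[1, i] <- record$quals[i]  # ambiguous: max over channels
    }
  }
  bases_block <- c(
    w_u32(ts$peak_index - 1L),        # peak offsets, 0-based
    w_u8(prob[1, ]), w_u8(prob[2, ]), w_u8(prob[3, ]), w_u8(prob[4, ]),
    w_chr(record$bases),
    as.raw(integer(3L * n)))          # prob_sub/ins/del spare
  header <- c(
    w_chr(".scf"), w_u32(tracelen), w_u32(samples_offset), w_u32(n),
    w_u32(0), w_u32(0),               # clips unused
    w_u32(bases_offset),
    w_u32(0), w_u32(bases_offset + length(bases_block)),  # comments
    w_chr("3.00"), w_u32(2),          # version, sample_size
    w_u32(4),                         # code set
    w_u32(0), w_u32(bases_offset + length(bases_block)),  # private
    w_u32(integer(18L)))              # spare
  samples <- do.call(c, lapply(c("A", "C", "G", "T"), function(ch) {
    w_u16(scf_delta_encode(ts$traces[[ch]], 16L))
  }))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, samples, bases_block), con)
  invisible(path)
}

# ---- synthetic SFF writer ----------------------------------------------

sff_flowgram <- function(bases, flow_chars) {
  fc <- strsplit(flow_chars, "")[[1]]
  nf <- length(fc)
  values <- integer(nf)
  index_per_base <- integer(nchar(bases))
  runs <- rle(strsplit(bases, "")[[1]])
  f <- 0L
  bi <- 0L
  for (k in seq_along(runs$values)) {
    steps <- 0L
    repeat {
      f <- f + 1L
      steps <- steps + 1L
      if (f > nf) stop("flow order too short for bases")
      if (fc[f] == runs$values[k]) break
    }
    values[f] <- 100L * runs$lengths[k]
    for (j in seq_len(runs$lengths[k])) {
      bi <- bi + 1L
      index_per_base[bi] <- if (j == 1L) steps else 0L
    }
  }
  list(values = values, index_per_base = index_per_base)
}

#' Write a synthetic SFF v1 file
#'
#' Flow values are synthesised from the base calls on a repeated `TACG`
#' flow order (100 units per incorporated base). Clip coordinates are taken
#' from each record's fields. The writer builds the big-endian layout
#' directly and shares no code with [read_sff()].
#'
#' @param records List of records (bases over ACGT, qualities). Clip fields
#'   (`clip_qual_left` etc.) are honoured when present, else written as 0.
#' @param path Output path.
#' @param flow_cycles Number of `TACG` cycles; defaults to enough for the
#'   longest read.
#' @return `path`, invisibly.
#' @export
write_synthetic_sff <- function(records, path, flow_cycles = NULL) {
  seqs <- vapply(records, function(r) r$bases, character(1))
  if (length(seqs) && any(grepl("[^ACGT]", seqs))) {
    stop("write_synthetic_sff: bases must be over ACGT")
  }
  if (is.null(flow_cycles)) {
    maxlen <- if (length(seqs)) max(nchar(seqs)) else 1L
    flow_cycles <- maxlen + 2L  # worst case: one cycle per base
  }
  flow_chars <- strrep("TACG", flow_cycles)
  nflows <- nchar(flow_chars)
  header <- c(
    as.raw(c(0x2e, 0x73, 0x66, 0x66)), w_u32(1),
    w_u32(0), w_u32(0),               # index offset (none)
    w_u32(0),                         # index length
    w_u32(length(records)),
    w_u16(0),                         # header_length placeholder
    w_u16(0),                         # key length
    w_u16(nflows), w_u8(1),
    w_chr(flow_chars))
  hlen <- length(header) + ((8L - length(header) %% 8L) %% 8L)
  header[25:26] <- w_u16(hlen)        # header_length field (bytes 25-26)
  header <- c(header, as.raw(integer(hlen - length(header))))
  body <- raw(0)
  for (r in records) {
    nb <- record_length(r)
    nml <- nchar(r$read_id)
    rhl <- 16L + nml
    rhl <- rhl + (8L - rhl %% 8L) %% 8L
    fg <- sff_flowgram(r$bases, flow_chars)
    clip <- function(field) {
      v <- r[[field]]
      if (is.null(v)) 0L else v
    }
    rhead <- c(w_u16(rhl), w_u16(nml), w_u32(nb),
               w_u16(clip("clip_qual_left")), w_u16(clip("clip_qual_right")),
               w_u16(clip("clip_adapter_left")),
               w_u16(clip("clip_adapter_right")),
               w_chr(r$read_id))
    rhead <- c(rhead, as.raw(integer(rhl - length(rhead))))
    rdata <- c(w_u16(fg$values), w_u8(fg$index_per_base),
               w_chr(r$bases), w_u8(r$quals))
    rdata <- c(rdata, pad8(length(rdata)))
    body <- c(body, rhead, rdata)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, body), con)
  invisible(path)
}

# ---- plain-text fixture writers (independent of seqio) ------------------

#' Write records as FASTQ at a chosen Phred offset (fixture writer)
#'
#' @param records List of records.
#' @param path Output path.
#' @param offset 33 or 64.
#' @return `path`, invisibly.
#' @export
write_fastq_fixture <- function(records, path, offset = 33L) {
  lines <- unlist(lapply(records, function(r) {
    c(paste0("@", r$read_id), r$bases, "+", intToUtf8(r$quals + offset))
  }))
  if (is.null(lines)) lines <- character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write records as FASTA + QUAL files (fixture writer)
#'
#' @param records List of records.
#' @param fasta_path,qual_path Output paths.
#' @param width Line wrap width.
#' @return `fasta_path`, invisibly.
#' @export
write_fasta_qual_fixture <- function(records, fasta_path, qual_path,
                                     width = 60L) {
  fa <- character(0)
  qu <- character(0)
  for (r in records) {
    fa <- c(fa, paste0(">", r$read_id))
    n <- record_length(r)
    starts <- seq(1L, max(n, 1L), by = width)
    if (n) {
      fa <- c(fa, substring(r$bases, starts, pmin(starts + width - 1L, n)))
    }
    qu <- c(qu, paste0(">", r$read_id))
    if (n) {
      qgrp <- split(r$quals, ceiling(seq_len(n) / width))
      qu <- c(qu, vapply(qgrp, paste, character(1), collapse = " "))
    }
  }
  writeLines(fa, fasta_path)
  writeLines(qu, qual_path)
  invisible(fasta_path)
}
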