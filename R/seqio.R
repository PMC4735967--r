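#' Detect the format of a sequencing file
#'
#' Classification is by magic bytes first (`"ABIF"`, `".scf"`, `".sff"` at
#' offset 0), then by text sniffing: a first non-blank line starting with
#' `@` followed by a `+` separator within the first record is FASTQ, a first
#' character `>` is a FASTA/QUAL candidate. Anything else, including files
#' shorter than 8 bytes or containing NUL bytes without a known magic, is
#' `"unknown"`.
#'
#' @param path Path to an existing readable file.
#' @return One of `"ab1"`, `"scf"`, `"sff"`, `"fastq"`, `"fasta_qual"`,
#'   `"unknown"`.
#' @export
detect_format <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  sz <- file.info(path)$size
  if (is.na(sz)) stop("cannot read '", path, "'")
  if (sz < 8) return("unknown")
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = min(sz, 4096))
  m4 <- head[1:4]
  if (identical(m4, charToRaw("ABIF"))) return("ab1")
  if (identical(m4, charToRaw(".scf"))) return("scf")
  if (identical(m4, as.raw(c(0x2e, 0x73, 0x66, 0x66)))) return("sff")
  if (any(head == as.raw(0L))) return("unknown")
  txt <- tryCatch(rawToChar(head), error = function(e) NA_character_)
  if (is.na(txt) || !validEnc(txt)) return("unknown")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return("unknown")
  first <- substr(trimws(lines[1]), 1, 1)
  if (is.na(first)) return("unknown")
  if (first == "@") {
    # a '+' separator line must appear within the first record (4 lines)
    sep <- which(substr(lines, 1, 1) == "+")
    if (length(sep) && sep[1] <= 4) return("fastq")
    return("unknown")
  }
  if (first == ">") return("fasta_qual")
  "unknown"
}

#' Detect the Phred encoding of a FASTQ file
#'
#' Scans the quality strings of up to `probe_reads` records. With `m` the
#' minimum quality character code observed: `m < 59` forces Phred+33;
#' codes 59-63 are illegal in standard Phred+64 so they also resolve to
#' Phred+33; when every code is >= 64 the file is taken as legacy Phred+64
#' and the decision is logged (Phred+33 data uniformly at Q >= 31 is
#' possible but rarer).
#'
#' @param path FASTQ file path.
#' @param probe_reads Number of records to probe (default 10000).
#' @return `"phred33"` or `"phred64"`.
#' @export
detect_fastq_encoding <- function(path, probe_reads = 10000L) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  lines <- readLines(path, n = 4L * probe_reads)
  lines <- drop_trailing_blank(lines)
  if (length(lines) < 4L) stop("'", path, "': no parsable FASTQ records")
  qlines <- lines[seq(4L, length(lines), by = 4L)]
  qlines <- qlines[nzchar(qlines)]
  if (!length(qlines)) stop("'", path, "': no parsable FASTQ records")
  m <- min(utf8ToInt(paste(qlines, collapse = "")))
  if (m < 64L) return("phred33")
  message("detect_fastq_encoding: all quality codes >= 64 in '", path,
          "'; resolving ambiguity as phred64")
  "phred64"
}

drop_trailing_blank <- function(lines) {
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  lines
}

#' Read a FASTQ file
#'
#' Parses strict 4-line records; the `+` line may repeat the identifier.
#' Qualities are the character codes minus the encoding offset (33 or 64);
#' a negative result is a parse error. Bases are upper-cased.
#'
#' @param path FASTQ file path.
#' @param encoding `"phred33"` or `"phred64"`; see [detect_fastq_encoding()].
#' @param pair_role Pair role assigned to every returned record.
#' @return List of [seq_record()]s in file order.
#' @export
read_fastq <- function(path, encoding = c("phred33", "phred64"),
                       pair_role = "single") {
  encoding <- match.arg(encoding)
  offset <- if (encoding == "phred33") 33L else 64L
  lines <- drop_trailing_blank(readLines(path))
  if (length(lines) %% 4L != 0L) {
    stop("'", path, "': truncated final FASTQ record (", length(lines),
         " lines)")
  }
  n <- length(lines) %/% 4L
  if (n == 0L) return(list())
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qstr <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(substr(hdr, 1, 1) != "@" | substr(plus, 1, 1) != "+")
  if (length(bad)) {
    stop("'", path, "': malformed FASTQ record at record ", bad[1])
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  ok <- grepl("^[ACGTUNRYSWKMBDHV]*$", seqs)
  if (!all(ok)) {
    stop("'", path, "': record '", ids[which(!ok)[1]],
         "': non-IUPAC characters in sequence")
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    q <- utf8ToInt(qstr[i]) - offset
    if (length(q) && min(q) < 0L) {
      stop("'", path, "': record '", ids[i],
           "': quality character below ", encoding, " offset (negative Phred)")
    }
    if (nchar(seqs[i]) != length(q)) {
      stop("'", path, "': record '", ids[i], "': ", nchar(seqs[i]),
           " bases but ", length(q), " qualities")
    }
    out[[i]] <- structure(
      list(read_id = ids[i], bases = seqs[i], quals = as.integer(q),
           pair_role = pair_role),
      class = "seq_record")
  }
  out
}

#' Read paired FASTA + QUAL files
#'
#' Records must appear in the same order with matching identifiers; the
#' number of quality values must equal the sequence length per record.
#'
#' @param fasta_path,qual_path Paths to the FASTA and QUAL files.
#' @param pair_role Pair role assigned to every returned record.
#' @return List of [seq_record()]s.
#' @export
read_fasta_qual <- function(fasta_path, qual_path, pair_role = "single") {
  fa <- parse_fasta_blocks(fasta_path)
  qu <- parse_fasta_blocks(qual_path)
  if (length(fa$ids) != length(qu$ids)) {
    stop("'", fasta_path, "' has ", length(fa$ids), " records but '",
         qual_path, "' has ", length(qu$ids))
  }
  out <- vector("list", length(fa$ids))
  for (i in seq_along(fa$ids)) {
    if (fa$ids[i] != qu$ids[i]) {
      stop("FASTA/QUAL pairing error at record ", i, ": id '", fa$ids[i],
           "' in FASTA vs '", qu$ids[i], "' in QUAL")
    }
    bases <- toupper(gsub("\\s", "", fa$bodies[i]))
    quals <- as.integer(strsplit(trimws(qu$bodies[i]), "\\s+")[[1]])
    if (nchar(bases) != length(quals)) {
      stop("record '", fa$ids[i], "': ", nchar(bases), " bases but ",
           length(quals), " quality values")
    }
    out[[i]] <- seq_record(fa$ids[i], bases, quals, pair_role)
  }
  out
}

parse_fasta_blocks <- function(path) {
  lines <- readLines(path)
  hdr <- which(substr(lines, 1, 1) == ">")
  if (!length(hdr)) stop("'", path, "': no FASTA records found")
  ids <- sub("\\s.*$", "", substring(lines[hdr], 2L))
  from <- hdr + 1L
  to <- c(hdr[-1L] - 1L, length(lines))
  bodies <- vapply(seq_along(hdr), function(i) {
    if (from[i] > to[i]) "" else paste(lines[from[i]:to[i]], collapse = " ")
  }, character(1))
  list(ids = ids, bodies = bodies)
}

#' Write records as Sanger-encoded (Phred+33) FASTQ
#'
#' Emits 4-line records with quality character `chr(q + 33)`. Qualities
#' above 93 are clamped to 93 with a warning. Output is byte-stable for
#' identical input.
#'
#' @param records List of [seq_record()]s.
#' @param path Output file path.
#' @return Number of records written, invisibly.
#' @export
write_fastq_sanger <- function(records, path) {
  n <- length(records)
  clamped <- FALSE
  lines <- character(4L * n)
  if (n) {
    for (i in seq_len(n)) {
      r <- records[[i]]
      q <- r$quals
      if (length(q) && max(q) > 93L) {
        clamped <- TRUE
        q <- pmin(q, 93L)
      }
      j <- 4L * (i - 1L)
      lines[j + 1L] <- paste0("@", r$read_id)
      lines[j + 2L] <- r$bases
      lines[j + 3L] <- "+"
      lines[j + 4L] <- intToUtf8(q + 33L)
    }
  }
  if (clamped) warning("qualities above 93 clamped to 93 in '", path, "'")
  con <- file(path, "wb")
  on.exit(close(con))
  if (n) writeLines(lines, con, sep = "\n")
  invisible(n)
}
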