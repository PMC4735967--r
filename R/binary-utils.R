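# Big-endian binary readers/writers shared by the ABIF/SCF/SFF parsers and
# the synthetic fixture writers. All `at` offsets are 1-based into a raw
# vector. Readers raise a truncation error instead of returning NAs.

read_file_raw <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  n <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = n)
}

check_span <- function(r, at, nbytes, what = "field") {
  if (at < 1 || at + nbytes - 1 > length(r)) {
    stop("truncated file: ", what, " at byte ", at, " runs past end (",
         length(r), " bytes)")
  }
}

ru8 <- function(r, at, n = 1L, what = "u8") {
  check_span(r, at, n, what)
  as.integer(r[at:(at + n - 1L)])
}

ru16 <- function(r, at, n = 1L, what = "u16") {
  check_span(r, at, 2L * n, what)
  readBin(r[at:(at + 2L * n - 1L)], "integer",
          n = n, size = 2L, endian = "big", signed = FALSE)
}

ru32 <- function(r, at, n = 1L, what = "u32") {
  check_span(r, at, 4L * n, what)
  v <- readBin(r[at:(at + 4L * n - 1L)], "integer",
               n = n, size = 4L, endian = "big")
  v <- as.numeric(v)
  ifelse(v < 0, v + 4294967296, v)
}

rchr <- function(r, at, n, what = "chars") {
  check_span(r, at, n, what)
  rawToChar(r[at:(at + n - 1L)])
}

# writers: build big-endian raw vectors (values -> bytes, vectorized)
w_u8 <- function(x) as.raw(as.integer(round(x)) %% 256L)

w_u16 <- function(x) {
  x <- as.integer(round(x)) %% 65536L
  as.raw(as.vector(rbind(x %/% 256L, x %% 256L)))
}

w_u32 <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(as.vector(rbind(floor(x / 16777216) %% 256,
                         floor(x / 65536) %% 256,
                         floor(x / 256) %% 256,
                         x %% 256)))
}

w_chr <- function(s) charToRaw(s)

# zero padding to an 8-byte boundary for a block of `len` bytes
pad8 <- function(len) as.raw(integer((8L - len %% 8L) %% 8L))
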