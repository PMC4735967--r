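# Independent brute-force oracles. These deliberately share no code with
# the implementation: plain loops, direct definitions.

oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av != bv)
}

# all-offsets ungapped adapter search: full placements anywhere, partial
# placements only as 3'-terminal prefixes of length >= min_overlap
oracle_locate_adapter <- function(read, adapter, kmer = 10L,
                                  max_mismatch = 2L, min_overlap = 5L) {
  la <- nchar(adapter)
  lr <- nchar(read)
  best <- NULL
  if (lr == 0L) return(NULL)
  for (o in 0:(lr - 1L)) {
    aligned <- min(la, lr - o)
    if (aligned < la && aligned < min_overlap) next
    mm <- oracle_hamming(substr(read, o + 1L, o + aligned),
                         substr(adapter, 1L, aligned))
    if (mm > ceiling(max_mismatch * aligned / la)) next
    if (is.null(best) || mm < best$mismatches) {
      best <- list(start = o + 1L, end = o + aligned, mismatches = mm)
    }
  }
  best
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
}

# O(n^2) duplicate filter: read i is removed if some kept earlier read j
# matches it under any active mode
oracle_duplicates <- function(keys, modes) {
  n <- length(keys)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dup <- FALSE
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if ("exact" %in% modes && keys[j] == keys[i]) dup <- TRUE
      if ("prefix" %in% modes && nchar(keys[j]) > nchar(keys[i]) &&
          substr(keys[j], 1, nchar(keys[i])) == keys[i]) dup <- TRUE
      if ("revcomp" %in% modes && keys[i] == oracle_revcomp(keys[j])) dup <- TRUE
      if (dup) break
    }
    keep[i] <- !dup
  }
  keep
}

# 3-mer self-similarity by explicit pairwise comparison of positions
oracle_dust <- function(s) {
  l <- nchar(s)
  if (l < 3L) return(0)
  raw <- 0
  for (i in 1:(l - 2L)) {
    for (j in seq_len(i - 1L)) {
      if (substr(s, i, i + 2L) == substr(s, j, j + 2L)) raw <- raw + 1
    }
  }
  maxraw <- (l - 2) * (l - 3) / 2
  if (maxraw <= 0) return(0)
  100 * raw / maxraw
}

oracle_entropy <- function(s) {
  l <- nchar(s)
  if (l < 3L) return(0)
  counts <- new.env(parent = emptyenv())
  for (i in 1:(l - 2L)) {
    k <- substr(s, i, i + 2L)
    counts[[k]] <- (if (is.null(counts[[k]])) 0 else counts[[k]]) + 1
  }
  cs <- unlist(mget(ls(counts), envir = counts))
  p <- cs / sum(cs)
  h <- -sum(p * log(p))
  norm <- log(min(l - 2, 64))
  if (norm <= 0) return(0)
  100 * h / norm
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
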