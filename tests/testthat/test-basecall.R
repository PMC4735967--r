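make_chrom <- function(bases, signals, quals = rep(30L, nchar(bases))) {
  # signals: list per position of named numeric c(A=,C=,G=,T=) or NULL for
  # a clean 1000-unit peak on the called base
  n <- nchar(bases)
  bvec <- strsplit(bases, "")[[1]]
  traces <- stats::setNames(rep(list(integer(n)), 4), c("A", "C", "G", "T"))
  for (i in seq_len(n)) {
    sig <- if (i <= length(signals) && !is.null(signals[[i]])) signals[[i]]
           else stats::setNames(1000 * (c("A", "C", "G", "T") == bvec[i]),
                                c("A", "C", "G", "T"))
    for (ch in names(sig)) traces[[ch]][i] <- sig[[ch]]
  }
  chromatogram_record("c", bases, quals, traces, "ACGT", seq_len(n))
}

test_that("competing channel pairs map to the stated two-base IUPAC codes", {
  # A/G unclear -> R; C/T unclear -> Y (and the other four pairs)
  pairs <- list(c("A", "G", "R"), c("C", "T", "Y"), c("C", "G", "S"),
                c("A", "T", "W"), c("G", "T", "K"), c("A", "C", "M"))
  for (p in pairs) {
    sig <- stats::setNames(c(10, 10, 10, 10), c("A", "C", "G", "T"))
    sig[p[1]] <- 1000
    sig[p[2]] <- 800
    ch <- make_chrom("N", list(sig))
    expect_identical(refine_ambiguous_calls(ch)$bases, p[3],
                     label = paste(p[1], p[2]))
  }
  # worked examples at ratio 0.5
  ch <- make_chrom("N", list(c(A = 1000, G = 950, C = 10, T = 5)))
  expect_identical(refine_ambiguous_calls(ch)$bases, "R")
  ch <- make_chrom("N", list(c(C = 800, T = 500, A = 5, G = 5)))
  expect_identical(refine_ambiguous_calls(ch)$bases, "Y")
  ch <- make_chrom("N", list(c(A = 1000, G = 100, C = 10, T = 10)))
  expect_identical(refine_ambiguous_calls(ch)$bases, "A")
})

test_that("three-channel and four-channel competition give B/D/H/V and N", {
  triples <- list(c("C", "G", "T", "B"), c("A", "G", "T", "D"),
                  c("A", "C", "T", "H"), c("A", "C", "G", "V"))
  for (tr in triples) {
    sig <- stats::setNames(c(5, 5, 5, 5), c("A", "C", "G", "T"))
    sig[tr[1:3]] <- c(1000, 900, 600)
    ch <- make_chrom("N", list(sig))
    expect_identical(refine_ambiguous_calls(ch)$bases, tr[4],
                     label = paste(tr[1:3], collapse = ""))
  }
  ch <- make_chrom("N", list(c(A = 1000, C = 990, G = 980, T = 970)))
  expect_identical(refine_ambiguous_calls(ch)$bases, "N")
  # all-zero signal stays N
  ch <- make_chrom("N", list(c(A = 0, C = 0, G = 0, T = 0)))
  expect_identical(refine_ambiguous_calls(ch)$bases, "N")
})

test_that("scope, length, qualities and non-N positions are preserved", {
  ch <- make_chrom("ANGA", list(NULL, c(A = 1000, G = 900, C = 0, T = 0)),
                   quals = c(40L, 7L, 35L, 30L))
  out <- refine_ambiguous_calls(ch)
  expect_identical(out$bases, "ARGA")
  expect_identical(out$quals, c(40L, 7L, 35L, 30L))
  expect_identical(nchar(out$bases), nchar(ch$bases))
  # all_positions re-calls confident bases too
  ch2 <- make_chrom("AA", list(c(A = 1000, C = 950, G = 0, T = 0), NULL))
  out2 <- refine_ambiguous_calls(
    ch2, ambiguity_params(recall_scope = "all_positions"))
  expect_identical(out2$bases, "MA")
  # n_only leaves the confident A untouched even with a competing channel
  expect_identical(refine_ambiguous_calls(ch2)$bases, "AA")
})

test_that("lowering ratio_threshold never shrinks the competing set", {
  set.seed(5)
  for (rep in 1:25) {
    sig <- stats::setNames(sample(0:1000, 4, replace = TRUE),
                           c("A", "C", "G", "T"))
    ch <- make_chrom("N", list(sig))
    ts <- c(1, 0.8, 0.5, 0.3, 0.1)
    sizes <- vapply(ts, function(t) {
      code <- refine_ambiguous_calls(ch, ambiguity_params(t))$bases
      sets <- c(A = 1, C = 1, G = 1, T = 1, R = 2, Y = 2, S = 2, W = 2,
                K = 2, M = 2, B = 3, D = 3, H = 3, V = 3, N = 4)
      sets[[code]]
    }, numeric(1))
    expect_true(all(diff(sizes) >= 0))
  }
  # ratio 1 with distinct signals: argmax base, never an ambiguity code
  set.seed(6)
  for (rep in 1:10) {
    sig <- stats::setNames(sample(1:1000, 4), c("A", "C", "G", "T"))
    ch <- make_chrom("N", list(sig))
    out <- refine_ambiguous_calls(ch, ambiguity_params(1))
    expect_identical(out$bases, names(sig)[which.max(sig)])
  }
})

test_that("planted ambiguity in a written trace file round-trips to the code", {
  td <- withr::local_tempdir()
  p <- file.path(td, "amb.ab1")
  write_synthetic_trace(seq_record("amb", "ANGT", c(30, 10, 30, 30)), "ab1", p,
                        secondary = list(list(pos = 2, bases = c("A", "G"),
                                              heights = c(1000, 900))))
  out <- refine_ambiguous_calls(read_chromatogram(p))
  expect_identical(out$bases, "ARGT")
})
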