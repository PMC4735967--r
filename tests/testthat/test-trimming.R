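qrec <- function(bases, quals = rep(30L, nchar(bases)), id = "t",
                 role = "single") {
  seq_record(id, bases, quals, role)
}

test_that("locate_adapter finds exact, substituted and terminal-partial occurrences", {
  ad <- "AGATCGGAAG"
  tp <- trim_params()
  # exact occurrence appended after a 10-base insert
  hit <- locate_adapter(paste0("ACGTACGTAC", ad), ad, tp)
  expect_identical(hit$start, 11L)
  expect_identical(hit$end, 20L)
  expect_identical(hit$mismatches, 0L)
  # one substitution: same coordinates, 1 mismatch
  ad1 <- paste0("AGATC", "T", "GAAG")  # G->T at position 6
  hit1 <- locate_adapter(paste0("ACGTACGTAC", ad1), ad, tp)
  expect_identical(hit1$start, 11L)
  expect_identical(hit1$end, 20L)
  expect_identical(hit1$mismatches, 1L)
  # 3'-terminal partial: first 6 adapter bases at the read end
  hit2 <- locate_adapter(paste0("CCTTGGCATCAA", substr(ad, 1, 6)), ad, tp)
  expect_identical(hit2$start, 13L)
  expect_identical(hit2$end, 18L)
  expect_identical(hit2$mismatches, 0L)
  # absent adapter is a NULL result, not an error
  expect_null(locate_adapter("CCTTGGCATCAATTGGCCAA", "AAAAAGGGGG", tp))
  expect_error(locate_adapter("ACGT", "", tp), "non-empty")
})

test_that("locate_adapter agrees with the brute-force all-offsets oracle", {
  set.seed(41)
  tp <- trim_params()
  for (i in 1:100) {
    adapter <- random_seq(sample(30:36, 1))
    read <- random_seq(sample(40:120, 1))
    # half the time, embed a mutated copy or a terminal prefix
    if (i %% 2 == 0) {
      pos <- sample(1:(nchar(read) - nchar(adapter)), 1)
      planted <- adapter
      for (k in seq_len(sample(0:2, 1))) {
        p <- sample(nchar(planted), 1)
        substr(planted, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                substr(planted, p, p)), 1)
      }
      substr(read, pos, pos + nchar(adapter) - 1L) <- planted
    }
    got <- locate_adapter(read, adapter, tp)
    want <- oracle_locate_adapter(read, adapter, tp$kmer, tp$max_mismatch,
                                  tp$min_overlap)
    expect_identical(got, want, label = paste("case", i))
  }
})

test_that("trim_adapters_primers applies the 5' primer and 3' adapter rules", {
  primer <- TEST_PRIMER
  adapter <- ILLUMINA_ADAPTER
  specs <- list(adapter_spec("primer", "P", primer),
                adapter_spec("adapter", "A", adapter))
  insert <- "TTGACCATGGATCCGGTTACGGATTGCCAGGA"
  r <- qrec(paste0(primer, insert, adapter))
  out <- trim_adapters_primers(r, specs)
  expect_identical(out$bases, insert)
  expect_identical(length(out$quals), nchar(insert))
  # 5' primer alone
  out5 <- trim_adapters_primers(qrec(paste0(primer, insert)), specs)
  expect_identical(out5$bases, insert)
  # 3' adapter mid-read removes everything downstream
  out3 <- trim_adapters_primers(qrec(paste0(insert, adapter, "GGCC")), specs)
  expect_identical(out3$bases, insert)
  # pure adapter read collapses to an empty record
  out0 <- trim_adapters_primers(qrec(adapter), specs)
  expect_identical(record_length(out0), 0L)
  # reverse-orientation features are searched as their reverse complement
  rspecs <- list(adapter_spec("adapter", "A", "", adapter))
  outr <- trim_adapters_primers(qrec(paste0(insert, revcomp(adapter))),
                                rspecs)
  expect_identical(outr$bases, insert)
})

test_that("terminal-N trimming removes only leading/trailing runs", {
  expect_identical(trim_terminal_ns(qrec("NNACGTNN"))$bases, "ACGT")
  expect_identical(trim_terminal_ns(qrec("ACNGT"))$bases, "ACNGT")
  expect_identical(record_length(trim_terminal_ns(qrec("NNNN"))), 0L)
  out <- trim_terminal_ns(qrec("NACGTN", c(2L, 30L, 31L, 32L, 33L, 2L)))
  expect_identical(out$quals, c(30L, 31L, 32L, 33L))
})

test_that("quality-end trimming drops low ends, keeps low interiors, and is idempotent", {
  r <- qrec("AAAAAAA", c(2L, 2L, 30L, 30L, 30L, 2L, 2L))
  out <- trim_quality_ends(r, 20, 1L)
  expect_identical(out$quals, c(30L, 30L, 30L))
  # no-op above threshold
  r2 <- qrec("ACGT", c(20L, 25L, 30L, 20L))
  expect_identical(trim_quality_ends(r2, 20, 1L)$quals, r2$quals)
  # interior low base kept
  r3 <- qrec("ACG", c(30L, 2L, 30L))
  expect_identical(trim_quality_ends(r3, 20, 1L)$quals, r3$quals)
  # windowed means and idempotence on random reads
  set.seed(43)
  for (i in 1:50) {
    q <- sample(2:40, sample(10:60, 1), replace = TRUE)
    r <- qrec(random_seq(length(q)), as.integer(q))
    once <- trim_quality_ends(r, 20, 5L)
    twice <- trim_quality_ends(once, 20, 5L)
    expect_identical(twice, once)
    expect_lte(record_length(once), record_length(r))
  }
})

test_that("planted primer+insert+adapter constructs trim back to the exact insert", {
  specs <- list(adapter_spec("primer", "P", TEST_PRIMER),
                adapter_spec("adapter", "A", ILLUMINA_ADAPTER))
  tp <- trim_params()
  sim <- generate_reads(100, quality_model = list(start = 38, end = 30,
                                                  sd = 1), seed = 44)
  pl <- plant_features(sim, primer = TEST_PRIMER, adapter = ILLUMINA_ADAPTER,
                       feature_mismatches = 0:2, seed = 45)
  for (i in seq_along(pl$reads)) {
    out <- trim_adapters_primers(pl$reads[[i]], specs, tp)
    expect_identical(out$bases, pl$truth$insert[i], label = paste("read", i))
  }
})

test_that("the full cascade never lengthens reads and is idempotent", {
  specs <- list(adapter_spec("adapter", "A", ILLUMINA_ADAPTER))
  tp <- trim_params()
  sim <- generate_reads(60, quality_model = list(start = 30, end = 8, sd = 4),
                        seed = 46)
  pl <- plant_features(sim, adapter = ILLUMINA_ADAPTER,
                       feature_mismatches = 0:1, seed = 47)
  for (r in pl$reads) {
    once <- trim_cascade(r, specs, tp)
    expect_lte(record_length(once), record_length(r))
    expect_identical(nchar(once$bases), length(once$quals))
    twice <- trim_cascade(once, specs, tp)
    expect_identical(twice, once)
  }
})
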