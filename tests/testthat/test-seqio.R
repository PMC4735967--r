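test_that("detect_format classifies magic bytes, FASTQ/FASTA sniffing and junk", {
  td <- withr::local_tempdir()
  ab1 <- file.path(td, "a.ab1")
  write_synthetic_trace(seq_record("a", "ACGT", c(20, 30, 40, 50)), "ab1", ab1)
  expect_identical(detect_format(ab1), "ab1")
  scf <- file.path(td, "a.scf")
  write_synthetic_trace(seq_record("a", "ACGT", c(20, 30, 40, 50)), "scf", scf)
  expect_identical(detect_format(scf), "scf")
  sff <- file.path(td, "a.sff")
  write_synthetic_sff(list(seq_record("a", "ACGT", c(20, 30, 40, 50))), sff)
  expect_identical(detect_format(sff), "sff")
  fq <- file.path(td, "a.fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
  expect_identical(detect_format(fq), "fastq")
  fa <- file.path(td, "a.fa")
  writeLines(c(">r1", "ACGT"), fa)
  expect_identical(detect_format(fa), "fasta_qual")
  junk <- file.path(td, "junk.bin")
  set.seed(9)
  writeBin(as.raw(sample(50:255, 256, replace = TRUE)), junk)
  expect_identical(detect_format(junk), "unknown")
  tiny <- file.path(td, "tiny")
  writeBin(as.raw(1:4), tiny)
  expect_identical(detect_format(tiny), "unknown")
  expect_error(detect_format(file.path(td, "nope")), "nope")
})

test_that("FASTQ offset arithmetic, encoding detection and error contracts", {
  td <- withr::local_tempdir()
  f33 <- file.path(td, "p33.fastq")
  writeLines(c("@r1", "ACGT", "+", "!!!I"), f33)
  expect_identical(read_fastq(f33, "phred33")[[1]]$quals, c(0L, 0L, 0L, 40L))
  f64 <- file.path(td, "p64.fastq")
  writeLines(c("@r1", "ACGT", "+", "@@@h"), f64)
  expect_identical(read_fastq(f64, "phred64")[[1]]$quals, c(0L, 0L, 0L, 40L))
  # '#' (code 35) forces phred33
  fhash <- file.path(td, "hash.fastq")
  writeLines(c("@r1", "ACGT", "+", "II#I"), fhash)
  expect_identical(detect_fastq_encoding(fhash), "phred33")
  # ';' (code 59) is illegal in phred64, resolves to phred33
  fsemi <- file.path(td, "semi.fastq")
  writeLines(c("@r1", "ACGT", "+", "II;I"), fsemi)
  expect_identical(detect_fastq_encoding(fsemi), "phred33")
  # all codes in [66, 104]: resolved as phred64 (and logged)
  expect_message(enc <- detect_fastq_encoding(f64), "phred64")
  expect_identical(enc, "phred64")
  # quality char ' ' (code 32) at phred33: negative Phred
  fbad <- file.path(td, "bad.fastq")
  writeLines(c("@r1", "ACGT", "+", "II I"), fbad)
  expect_error(read_fastq(fbad, "phred33"), "negative")
  # base/quality length mismatch names the record
  fmis <- file.path(td, "mis.fastq")
  writeLines(c("@r7", "ACGT", "+", "III"), fmis)
  expect_error(read_fastq(fmis, "phred33"), "r7")
  # truncated final record
  ftr <- file.path(td, "tr.fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), ftr)
  expect_error(read_fastq(ftr, "phred33"), "truncated")
  expect_error(detect_fastq_encoding(file.path(td, "empty.fastq")),
               "no such file|cannot", ignore.case = TRUE)
})

test_that("write_fastq_sanger encodes, clamps and round-trips", {
  td <- withr::local_tempdir()
  out <- file.path(td, "out.fastq")
  write_fastq_sanger(list(seq_record("r1", "ACGT", c(0, 20, 40, 93))), out)
  expect_identical(readLines(out), c("@r1", "ACGT", "+", "!5I~"))
  # empty stream: file created, zero records
  empty <- file.path(td, "empty.fastq")
  expect_identical(write_fastq_sanger(list(), empty), 0L)
  expect_true(file.exists(empty))
  expect_identical(length(readLines(empty)), 0L)
  # phred64 input -> sanger output preserves integer qualities
  f64 <- file.path(td, "in64.fastq")
  set.seed(21)
  recs <- make_fastq_records(30, seed = 21)
  write_fastq_fixture(recs, f64, 64L)
  conv <- file.path(td, "conv.fastq")
  write_fastq_sanger(read_fastq(f64, "phred64"), conv)
  back <- read_fastq(conv, "phred33")
  for (i in seq_along(recs)) {
    expect_identical(back[[i]]$quals, recs[[i]]$quals)
    expect_identical(back[[i]]$bases, recs[[i]]$bases)
  }
  # byte-stable output
  conv2 <- file.path(td, "conv2.fastq")
  write_fastq_sanger(read_fastq(f64, "phred64"), conv2)
  expect_identical(unname(tools::md5sum(conv)), unname(tools::md5sum(conv2)))
})

test_that("FASTA+QUAL pairing enforces ids and per-record lengths", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "a.fa")
  qu <- file.path(td, "a.qual")
  writeLines(c(">r1", "ACGT"), fa)
  writeLines(c(">r1", "20 20 20 20"), qu)
  rec <- read_fasta_qual(fa, qu)[[1]]
  expect_identical(rec$bases, "ACGT")
  expect_identical(rec$quals, rep(20L, 4))
  writeLines(c(">r1", "20 20 20"), qu)
  expect_error(read_fasta_qual(fa, qu), "r1")
  writeLines(c(">r2", "20 20 20 20"), qu)
  expect_error(read_fasta_qual(fa, qu), "r1.*r2")
})

test_that("ABIF reader recovers planted bases/quals and honours FWO_ channel order", {
  td <- withr::local_tempdir()
  p <- file.path(td, "t.ab1")
  rec <- seq_record("t", "ACGT", c(20, 30, 40, 50))
  write_synthetic_trace(rec, "ab1", p)
  got <- read_chromatogram(p, "ab1")
  expect_identical(got$bases, "ACGT")
  expect_identical(got$quals, c(20L, 30L, 40L, 50L))
  # planted per-channel truth: G-called base peaks on the G channel, which
  # under FWO_="GATC" is the first trace array
  p2 <- file.path(td, "g.ab1")
  ref <- write_synthetic_trace(seq_record("g", "GGCA", rep(30L, 4)), "ab1", p2,
                               channel_order = "GATC")
  got2 <- read_chromatogram(p2)
  expect_identical(got2$channel_order, "GATC")
  truth <- attr(ref, "traces")
  expect_identical(got2$traces[[1]], truth[["G"]])
  expect_identical(got2$traces[[2]], truth[["A"]])
  sig <- vapply(got2$traces, function(tr) tr[got2$peak_index[1]], integer(1))
  expect_identical(strsplit(got2$channel_order, "")[[1]][which.max(sig)], "G")
  # error contracts
  bad <- file.path(td, "bad.ab1")
  writeBin(charToRaw("NOPEnotanabif_file_at_all_padding_pad"), bad)
  expect_error(read_chromatogram(bad, "ab1"), "magic")
  raw <- readBin(p, "raw", file.size(p))
  # corrupt the PBAS tag name so the mandatory tag is missing
  pbas_at <- grepRaw("PBAS", raw, all = TRUE)
  raw[pbas_at[length(pbas_at)]] <- as.raw(88)
  writeBin(raw, bad)
  expect_error(read_chromatogram(bad, "ab1"), "PBAS")
  writeBin(raw[1:40], bad)
  expect_error(read_chromatogram(bad, "ab1"), "truncated|magic")
})

test_that("SCF v3 reader recovers planted data; pre-v3 files are rejected", {
  td <- withr::local_tempdir()
  p <- file.path(td, "t.scf")
  write_synthetic_trace(seq_record("t", "NNGA", c(2, 3, 40, 41)), "scf", p)
  got <- read_chromatogram(p, "scf")
  expect_identical(got$bases, "NNGA")
  expect_identical(got$quals, c(2L, 3L, 40L, 41L))
  expect_identical(got$channel_order, "ACGT")
  expect_true(all(diff(got$peak_index) > 0))
  raw <- readBin(p, "raw", file.size(p))
  raw[37:40] <- charToRaw("2.00")
  bad <- file.path(td, "v2.scf")
  writeBin(raw, bad)
  expect_error(read_chromatogram(bad, "scf"), "version")
})

test_that("SFF reader yields records in order, preserves clips, handles empty files", {
  td <- withr::local_tempdir()
  p <- file.path(td, "t.sff")
  recs <- list(
    flow_record("f1", "ACGTACGT", rep(30L, 8), integer(0), "",
                clip_qual_left = 5L),
    seq_record("f2", "TTGGCCAA", rep(20L, 8)),
    seq_record("f3", "ACACACGT", rep(25L, 8)))
  write_synthetic_sff(recs, p)
  got <- read_sff(p)
  expect_identical(vapply(got, function(r) r$read_id, character(1)),
                   c("f1", "f2", "f3"))
  expect_identical(got[[1]]$clip_qual_left, 5L)
  expect_identical(got[[1]]$clip_qual_right, 0L)
  expect_identical(got[[2]]$bases, "TTGGCCAA")
  # vendor clips applied at conversion: left clip 5 drops first 4 bases
  clipped <- seqsanitize:::apply_sff_clips(got[[1]])
  expect_identical(clipped$bases, "ACGT")
  # empty SFF: valid header, zero reads, no error
  e <- file.path(td, "e.sff")
  write_synthetic_sff(list(), e)
  expect_identical(read_sff(e), list())
  # version check
  raw <- readBin(p, "raw", file.size(p))
  raw[8] <- as.raw(2)
  bad <- file.path(td, "v2.sff")
  writeBin(raw, bad)
  expect_error(read_sff(bad), "version")
})

test_that("random format round-trips recover planted records exactly", {
  td <- withr::local_tempdir()
  set.seed(31)
  sim <- generate_reads(40, seed = 31)
  for (i in seq_len(10)) {
    for (fmt in c("ab1", "scf")) {
      p <- file.path(td, sprintf("%d.%s", i, fmt))
      write_synthetic_trace(sim$reads[[i]], fmt, p)
      got <- read_chromatogram(p)
      expect_identical(got$bases, sim$reads[[i]]$bases)
      expect_identical(got$quals, sim$reads[[i]]$quals)
    }
  }
  sffp <- file.path(td, "all.sff")
  write_synthetic_sff(sim$reads, sffp)
  got <- read_sff(sffp)
  for (i in seq_along(sim$reads)) {
    expect_identical(got[[i]]$bases, sim$reads[[i]]$bases)
    expect_identical(got[[i]]$quals, sim$reads[[i]]$quals)
  }
  fqp <- file.path(td, "all.fastq")
  write_fastq_fixture(sim$reads, fqp, 33L)
  got <- read_fastq(fqp, "phred33")
  fap <- file.path(td, "all.fa")
  qup <- file.path(td, "all.qual")
  write_fasta_qual_fixture(sim$reads, fap, qup)
  gfq <- read_fasta_qual(fap, qup)
  for (i in seq_along(sim$reads)) {
    expect_identical(got[[i]]$quals, sim$reads[[i]]$quals)
    expect_identical(gfq[[i]]$bases, sim$reads[[i]]$bases)
    expect_identical(gfq[[i]]$quals, sim$reads[[i]]$quals)
  }
})
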