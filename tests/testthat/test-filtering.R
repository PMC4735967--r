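frec <- function(bases, quals = rep(30L, nchar(bases)), id = "f") {
  seq_record(id, bases, quals)
}

test_that("duplicate modes: exact collapse, prefix removal, revcomp removal", {
  reads <- list(frec("ACGTACGT", id = "a"), frec("ACGTACGT", id = "b"),
                frec("ACGTACGT", id = "c"))
  res <- filter_duplicates(reads, "exact")
  expect_identical(length(res$kept), 1L)
  expect_identical(res$removed_count, 2L)
  expect_identical(res$kept[[1]]$read_id, "a")  # first occurrence kept
  # a read equal to a 5' prefix of an already-kept longer read is removed
  pre <- filter_duplicates(list(frec("ACGTACGT"), frec("ACGTAC")), "prefix")
  expect_identical(pre$removed_count, 1L)
  # but a longer read arriving after its prefix is kept
  pre2 <- filter_duplicates(list(frec("ACGTAC"), frec("ACGTACGT")), "prefix")
  expect_identical(pre2$removed_count, 0L)
  # reverse-complement duplicates
  rc <- filter_duplicates(list(frec("AAGC"), frec("GCTT")), "revcomp")
  expect_identical(rc$removed_count, 1L)
  expect_identical(rc$kept[[1]]$bases, "AAGC")
})

test_that("duplicate filter matches the O(n^2) oracle for every mode combination", {
  set.seed(51)
  keys <- vapply(1:120, function(i) {
    random_seq(sample(6:12, 1))
  }, character(1))
  # force collisions: duplicates, prefixes and revcomps of earlier reads
  for (i in sample(30:120, 40)) {
    j <- sample(i - 1L, 1)
    keys[i] <- switch(sample(3, 1),
                      keys[j],
                      substr(keys[j], 1, max(3, nchar(keys[j]) - 2L)),
                      oracle_revcomp(keys[j]))
  }
  combos <- list("exact", "prefix", "revcomp", c("exact", "prefix"),
                 c("exact", "revcomp"), c("prefix", "revcomp"),
                 c("exact", "prefix", "revcomp"))
  for (modes in combos) {
    got <- seqsanitize:::duplicate_mask(keys, modes)
    want <- oracle_duplicates(keys, modes)
    expect_identical(got, want, label = paste(modes, collapse = "+"))
  }
})

test_that("complexity scores hit forced extremes and match 3-mer oracles", {
  expect_equal(complexity_score(strrep("A", 10), "dust"), 100)
  expect_equal(complexity_score(strrep("A", 10), "entropy"), 0)
  expect_equal(complexity_score("AC", "dust"), 0)  # shorter than a 3-mer
  expect_error(complexity_score("ACGT-", "dust"), "non-IUPAC")
  set.seed(52)
  for (i in 1:60) {
    s <- random_seq(sample(10:80, 1),
                    alphabet = if (i %% 3 == 0) c("A", "C") else
                      c("A", "C", "G", "T"))
    expect_equal(complexity_score(s, "dust"), oracle_dust(s),
                 tolerance = 1e-12, label = paste("dust", i))
    expect_equal(complexity_score(s, "entropy"), oracle_entropy(s),
                 tolerance = 1e-12, label = paste("entropy", i))
  }
  # a sequence whose 3-mers are all distinct scores dust 0 / entropy 100
  s <- "AACAGATCCGCTGGTTA"  # de Bruijn-style fragment, 15 distinct 3-mers
  expect_identical(length(unique(substring(s, 1:15, 3:17))), 15L)
  expect_equal(complexity_score(s, "dust"), 0)
  expect_equal(complexity_score(s, "entropy"), 100)
})

test_that("passes_filters enforces thresholds and reports the first failure", {
  fp <- filter_params(min_mean_q = 20, min_len = 1L)
  expect_true(passes_filters(frec("ACGT", c(20L, 20L, 20L, 20L)), fp)$pass)
  v <- passes_filters(frec("AC", c(10L, 20L)), fp)
  expect_false(v$pass)
  expect_identical(v$criterion, "min_mean_q")
  fp50 <- filter_params(min_len = 50L)
  v2 <- passes_filters(frec(random_seq(49)), fp50)
  expect_false(v2$pass)
  expect_identical(v2$criterion, "min_len")
  fpmax <- filter_params(min_len = 1L, max_len = 10L)
  expect_identical(passes_filters(frec(random_seq(11)), fpmax)$criterion,
                   "max_len")
  # low-complexity read fails under dust, passes when screening is off
  homop <- frec(strrep("A", 60))
  fpc <- filter_params(min_len = 1L)
  expect_identical(passes_filters(homop, fpc)$criterion, "complexity")
  fpoff <- filter_params(min_len = 1L, apply_complexity = FALSE)
  expect_true(passes_filters(homop, fpoff)$pass)
})

test_that("pair synchronisation keeps exactly the pairs whose both mates survive", {
  fwd <- list(frec("AAAA", id = "r1/1"), frec("CCCC", id = "r2/1"),
              frec("GGGG", id = "r3/1"))
  rev <- list(frec("TTTT", id = "r1/2"), frec("ACAC", id = "r2/2"),
              frec("AGAG", id = "r3/2"))
  out <- synchronize_pairs(fwd, rev, survivors = list(
    fwd = c("r1", "r2", "r3"), rev = c("r1", "r3")))
  ids <- function(x) seqsanitize:::strip_mate_suffix(
    vapply(x, function(r) r$read_id, character(1)))
  expect_identical(ids(out$fwd), c("r1", "r3"))
  expect_identical(ids(out$fwd), ids(out$rev))
  # disjoint survivor sets give an empty output
  empty <- synchronize_pairs(fwd, rev, survivors = list(fwd = "r1",
                                                        rev = "r2"))
  expect_identical(length(empty$fwd), 0L)
  # identical survivor sets preserve input order
  full <- synchronize_pairs(fwd, rev)
  expect_identical(ids(full$fwd), c("r1", "r2", "r3"))
  # Casava-style space suffixes normalise too
  fwd2 <- list(frec("AAAA", id = "x 1:N:0:ACGT"))
  rev2 <- list(frec("TTTT", id = "x 2:N:0:ACGT"))
  both <- synchronize_pairs(fwd2, rev2)
  expect_identical(length(both$fwd), 1L)
  # duplicate ids on one side are an error naming the id
  expect_error(synchronize_pairs(c(fwd, fwd[1]), rev), "r1")
})

test_that("kept + per-criterion removed reads account for every input read", {
  set.seed(53)
  sim <- generate_reads(400, length_model = list(min = 30L, max = 90L),
                        quality_model = list(start = 30, end = 12, sd = 6),
                        seed = 53)
  reads <- sim$reads
  # salt in low-complexity reads
  for (i in sample(400, 30)) {
    reads[[i]] <- frec(strrep("AT", 30), id = reads[[i]]$read_id)
  }
  fp <- filter_params(min_len = 50L)
  tally <- c(min_len = 0L, max_len = 0L, min_mean_q = 0L, complexity = 0L)
  kept <- 0L
  for (r in reads) {
    v <- passes_filters(r, fp)
    if (v$pass) kept <- kept + 1L else tally[v$criterion] <- tally[v$criterion] + 1L
  }
  expect_identical(kept + sum(tally), 400L)
  expect_gt(tally["min_len"], 0L)
  expect_gt(tally["complexity"], 0L)
  # every kept read satisfies all thresholds
  for (r in reads) {
    v <- passes_filters(r, fp)
    if (v$pass) {
      expect_gte(mean(r$quals), fp$min_mean_q)
      expect_gte(record_length(r), fp$min_len)
      expect_lte(complexity_score(r$bases, "dust"), fp$complexity_threshold)
    }
  }
})
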