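# Builders for small synthetic cohorts used by pipeline and acceptance
# tests. All files are created under a fresh temporary directory.

ILLUMINA_ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"
TEST_PRIMER <- "ACACTGACGACATGGTTCTACA"

make_fastq_records <- function(n, seed, len = c(80L, 120L),
                               q = list(start = 35, end = 25, sd = 3),
                               id_prefix = "read") {
  generate_reads(n, length_model = list(min = len[1], max = len[2]),
                 quality_model = q, seed = seed, id_prefix = id_prefix)$reads
}

# Writes a mixed Sanger + Illumina (pooled, paired) + SFF cohort and
# returns the target/adapter file paths. `n_samples` counts manifest rows.
build_mixed_cohort <- function(dir, seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  bc <- suppressWarnings(
    barcode_table(paste0("ILL", 1:4),
                  c("ACGTACGT", "TGCATGCA", "GGAACCTT", "CAGTCAGT")))
  sim <- generate_reads(120, seed = seed + 1L)
  assignments <- sample(c(bc$sample_id, NA), 120, replace = TRUE)
  pl <- plant_features(sim, barcodes = bc, assignments = assignments,
                       primer = TEST_PRIMER, adapter = ILLUMINA_ADAPTER,
                       feature_mismatches = 0:2, seed = seed + 2L)
  rev <- generate_reads(120, seed = seed + 3L)$reads
  for (i in seq_along(rev)) rev[[i]]$read_id <- pl$reads[[i]]$read_id
  r1 <- file.path(dir, "pool_R1.fastq")
  r2 <- file.path(dir, "pool_R2.fastq")
  write_fastq_fixture(pl$reads, r1, 33L)
  write_fastq_fixture(rev, r2, 64L)

  sanger_rows <- lapply(1:4, function(k) {
    s <- generate_reads(3, length_model = list(min = 150L, max = 250L),
                        quality_model = list(start = 40, end = 30, sd = 2),
                        seed = seed + 10L + k,
                        id_prefix = sprintf("trace%d", k))
    paths <- vapply(seq_along(s$reads), function(i) {
      fmt <- if (i %% 2L == 0L) "scf" else "ab1"
      p <- file.path(dir, sprintf("s%d_%d.%s", k, i, fmt))
      write_synthetic_trace(s$reads[[i]], fmt, p)
      p
    }, character(1))
    list(id = paste0("SAN", k), paths = paths)
  })

  sff_rows <- lapply(1:2, function(k) {
    reads <- generate_reads(25, seed = seed + 20L + k,
                            id_prefix = sprintf("flow%d", k))$reads
    p <- file.path(dir, sprintf("ion%d.sff", k))
    write_synthetic_sff(reads, p)
    list(id = paste0("ION", k), path = p)
  })

  target <- file.path(dir, "target.tsv")
  lines <- c("Patient_ID\tPlatform\tRead1\tRead2\tMID\tTissue")
  for (i in 1:4) {
    lines <- c(lines, sprintf("ILL%d\tillumina\t%s\t%s\t%s\tblood", i,
                              basename(r1), basename(r2), bc$mid[i]))
  }
  for (s in sanger_rows) {
    lines <- c(lines, sprintf("%s\tsanger\t%s\t\t\t", s$id,
                              paste(basename(s$paths), collapse = ";")))
  }
  for (s in sff_rows) {
    lines <- c(lines, sprintf("%s\t454\t%s\t\t\t", s$id, basename(s$path)))
  }
  writeLines(lines, target)

  adapters <- file.path(dir, "adapters.tsv")
  writeLines(c(paste("adapter", "A1", ILLUMINA_ADAPTER, "", sep = "\t"),
               paste("primer", "PR1", TEST_PRIMER, "", sep = "\t")),
             adapters)
  list(target = target, adapters = adapters, barcodes = bc,
       truth = pl$truth, n_samples = 10L)
}
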