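Package: seqsanitize
Title: Quality Control, Format Conversion and Cleaning of Sanger and NGS Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated quality-control pipeline for clinical sequencing data.
    Reads Sanger chromatograms (AB1/ABIF and SCF v3), 454/Ion Torrent flowgrams
    (SFF v1, FASTA+QUAL) and Illumina FASTQ (Phred+33 or Phred+64), converts
    everything to Sanger-encoded FASTQ, refines ambiguous Sanger base calls from
    trace signals, demultiplexes barcoded pools, trims adapters, primers,
    terminal Ns and low-quality ends, removes duplicate and low-complexity
    reads, enforces paired-end consistency, and renders per-sample before/after
    QC reports plus a cohort summary table. A synthetic-data module writes valid
    files in every supported format with planted, machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    parallel,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
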