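# seqsanitize

Quality control, format unification and cleaning of Sanger and
next-generation sequencing reads, built for clinical cohorts in which the
same study mixes capillary Sanger traces (mutation confirmation) with
Illumina, 454 or Ion Torrent short reads (mutation discovery). Every
sample, whatever its instrument, leaves the pipeline as a Sanger-encoded
(Phred+33) FASTQ of high-quality reads plus a before/after QC report, and
the cohort leaves as a one-row-per-sample summary table — so downstream
mutation screening sees one uniform input model.

## What it does

For each sample the pipeline runs the platform-appropriate stages:

| Stage | Sanger | NGS |
|---|---|---|
| Trace parsing (AB1/ABIF, SCF v3) and ambiguous-call refinement | ✓ | – |
| Conversion to Phred+33 records (SFF v1, FASTA+QUAL, FASTQ ±33/64) | ✓ | ✓ |
| Barcode (MID) demultiplexing | – | ✓ |
| Adapter / primer trimming (mismatch-tolerant, k-mer seeded) | ✓ | ✓ |
| Duplicate removal (exact / prefix / reverse-complement) | – | ✓ |
| Low-complexity ("contamination") screening | – | ✓ |
| Terminal-N and low-quality end trimming | ✓ | ✓ |
| Length / mean-quality filtering with exact removal accounting | ✓ | ✓ |
| Paired-end consistency (lose one mate → lose the pair) | – | ✓ |
| QC statistics, per-sample reports, cohort summary | ✓ | ✓ |

Two of the stages carry the package's normative algorithms:

* **Ambiguous base-call refinement.** At every position the Sanger base
  caller left as N, the four trace signals at the peak position are
  compared; channels with signal ≥ `ratio_threshold` × the strongest
  (default 0.5) form the competing set, re-called as its IUPAC code — R
  for A/G, Y for C/T, …, B/D/H/V for three-base sets, N for four or none.
* **Adapter matching.** Ungapped k-mer-seeded alignment plus explicit
  3'-terminal prefix placements, accepting a placement with mismatches ≤
  `ceil(max_mismatch · aligned_length / adapter_length)`; fewest
  mismatches wins, ties leftmost. Primers are anchored within the first
  3 bases of the read and trim the 5' end; adapters trim to the 3' end.

Low-complexity screening scores overlapping 3-mers on a 0–100 scale:
DUST `100·Σ c_t(c_t−1)/2 / [(L−2)(L−3)/2]` (homopolymer = 100, fail > 7)
or normalised Shannon entropy (homopolymer = 0, fail < 30).

A synthetic-data module generates valid AB1, SCF, SFF, FASTA+QUAL and
FASTQ files with planted, machine-readable ground truth (barcodes,
feature positions, substitution counts, quality decay). Its writers share
no code with the readers, so the test suite's round-trips compare two
independent implementations of every byte format.

## Worked example

Three patients: two Illumina samples pooled in one barcoded FASTQ, one
Sanger AB1 trace. (Here the inputs are generated by the package's own
fixture module; real files drop in identically.)

```r
library(seqsanitize)

bc  <- barcode_table(c("PatientA", "PatientB"), c("ACGTACGT", "TGCATGCA"))
sim <- generate_reads(200, seed = 7)
set.seed(7)
assignments <- sample(c("PatientA", "PatientB", NA), 200, replace = TRUE)
pool <- plant_features(sim, barcodes = bc, assignments = assignments,
                       adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                       feature_mismatches = 0:2, seed = 8)
write_fastq_fixture(pool$reads, "pool.fastq", 33L)
trace <- generate_reads(1, length_model = list(min = 180L, max = 220L),
                        quality_model = list(start = 40, end = 30, sd = 2),
                        seed = 9)$reads[[1]]
write_synthetic_trace(trace, "ab1", "patientC.ab1")
writeLines(c("Patient_ID\tPlatform\tRead1\tMID\tTissue",
             "PatientA\tillumina\tpool.fastq\tACGTACGT\tblood",
             "PatientB\tillumina\tpool.fastq\tTGCATGCA\ttumor",
             "PatientC\tsanger\tpatientC.ab1\t\tblood"), "target.tsv")
writeLines("adapter\tTruSeq\tAGATCGGAAGAGCACACGTCTGAACTCCAGTCA\t",
           "adapters.tsv")

run <- run_pipeline(parse_target_file("target.tsv"),
                    parse_adapter_file("adapters.tsv"),
                    pipeline_config(), "qc_out")
print(run)
```

```
<pipeline_run> 3 samples, 0 failed; summary: qc_out/summary.tsv
```

and `qc_out/summary.tsv` holds one row per patient:

```
Patient_ID  status  reads_before  reads_after  gc_before  gc_after  report_before         report_after         fastq           Tissue
PatientA    ok      63            63           50.9512    50.7613   PatientA_before.html  PatientA_after.html  PatientA.fastq  blood
PatientB    ok      73            73           50.2335    49.8186   PatientB_before.html  PatientB_after.html  PatientB.fastq  tumor
PatientC    ok      1             1            53.5135    53.5135   PatientC_before.html  PatientC_after.html  PatientC.fastq  blood
```

Reading the rows: the 200 pooled reads demultiplexed into 63 for
PatientA, 73 for PatientB (the remainder were barcode-free and land in the
unassigned bin); all survived QC because the simulated qualities are
healthy, while the planted adapters were trimmed off — visible as the
small GC shift between `gc_before` and `gc_after`. Each row links the
patient's before/after QC reports and final Phred+33 FASTQ;
`run$results[[i]]$removed` holds the per-criterion removal counts, which
always sum with `reads_after` to `reads_before`.

The same run is available from a shell:

```sh
exec/seqsanitize run --target target.tsv --adapters adapters.tsv --out qc_out
```

with stage-level subcommands `convert`, `demux`, `trim`, `filter` and
`stats` for one-off use.

## Further reading

`vignettes/seqsanitize-methods.Rmd` documents the algorithms, parameter
defaults and their rationale, the synthetic-data model and its limits,
numerical conventions, and known limitations.
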