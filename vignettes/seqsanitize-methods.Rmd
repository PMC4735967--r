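---
title: "Methods and design of the seqsanitize QC pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the seqsanitize QC pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqsanitize)
```

## Scope and model of the pipeline

seqsanitize is a quality-control and format-unification pipeline for
clinical sequencing cohorts that mix capillary Sanger traces with short-read
data from Illumina, 454 and Ion Torrent instruments. Each sample travels
through a fixed, platform-appropriate stage order and ends as a
Sanger-encoded (Phred+33) FASTQ file plus a before/after QC report; the
cohort ends as a one-row-per-sample summary table.

* **Sanger rows**: read trace (AB1 or SCF v3) → refine ambiguous base calls
  from the trace signals → convert → trim primers/adapters → trim terminal
  Ns and low-quality ends → filter on length and mean quality → report.
* **NGS rows**: convert to records → demultiplex by 5' barcode (unless the
  manifest marks the input as already demultiplexed) → trim
  adapters/primers → remove duplicates → screen low-complexity reads → trim
  ends → filter → synchronise pairs → report.

Base-call refinement applies only to Sanger data (only chromatograms carry
trace signals); demultiplexing and duplicate/contamination screening apply
only to NGS data, where multiplexing and PCR amplification are the sources
of those artifacts. The pipeline contains no randomised step, so results
are identical for any worker count and manifest order; this is asserted by
tests rather than assumed.

## File formats

The package parses the three binary containers natively:

* **ABIF (AB1)**: big-endian tagged container. Base calls are taken from
  `PBAS.1`, per-base qualities from `PCON.1`, peak positions from `PLOC.1`,
  the channel order from `FWO_.1`, and the four *analysed* trace arrays
  from `DATA.9`–`DATA.12`. The raw traces `DATA.1`–`DATA.8` are ignored:
  the number-9-to-12 entries are the de facto convention for processed
  data, and the peak-ratio rule below is defined on analysed signals. An
  AB1 file lacking `PCON` is rejected rather than assigned invented
  qualities.
* **SCF**: only version ≥ 3.00 is supported (planar channel layout,
  double-delta-encoded samples). Version 2 interleaving adds little in
  practice and is rejected with a clear error.
* **SFF v1**: big-endian flowgram container. The reader preserves the four
  vendor clip coordinates verbatim; clips are *applied* at conversion time
  (first usable base `max(clip_qual_left, clip_adapter_left)`, last usable
  base the minimum of the non-zero right clips), because vendor clips
  encode instrument knowledge that should precede any further trimming.

FASTQ offset detection uses the minimum observed quality character code
`m`: `m < 59` can only be Phred+33; codes 59–63 are illegal in standard
Phred+64 and also resolve to Phred+33; when every code is ≥ 64 the file is
taken as legacy Phred+64 and the decision is logged. The residual ambiguity
(a Phred+33 file uniformly at Q ≥ 31) is real but rare, and the
`seqio.encoding` option overrides detection. Qualities above 93 are clamped
to the Sanger-encodable ceiling with a warning rather than rejected:
lossy, but it preserves reads and stays auditable.

## Ambiguous base-call refinement

Sanger base callers report any unclear peak as N even when the trace
restricts the call to two or three nucleotides. seqsanitize re-examines
each in-scope position with a transparent peak-ratio rule: read the four
channel signals at the base's peak position; every channel with signal at
least `ratio_threshold` × the strongest signal joins the competing set; the
position is re-called as the IUPAC code of that set (two bases give
R/Y/S/W/K/M, three give B/D/H/V, four — or an all-zero peak — stays N).

Defaults: `ratio_threshold = 0.5`, scope `n_only`. A secondary peak at
half the primary height is the conventional boundary between background
and a genuine secondary signal in mixed-template traces; re-calling
*confident* bases (`all_positions`) is opt-in because overriding the
instrument's calls is a stronger intervention than refining its explicit
"don't know". Signals are compared at the single peak sample, not a
window average: the synthetic traces the rule is validated against have
well-formed peaks, and a window would add a smoothing parameter without a
ground truth to calibrate it. The rule is deliberately simple and
deterministic — it is a refinement of reported ambiguity, not a
re-basecall, and it does not attempt statistically calibrated heterozygote
detection.

## Demultiplexing

Barcodes (MIDs) are anchored at the 5' end of the forward read. Matching
is Hamming distance over the equal-length read prefix, with N counting as
a mismatch. Lengths are tried longest-first so that nested barcode sets
resolve to the most specific match; within a length, a unique
minimum-distance candidate within `max_mismatch` wins and any tie leaves
the read unassigned — in a clinical context, assigning a read to the wrong
patient is far worse than dropping it. On assignment the barcode bases and
their qualities are removed. For paired input only the forward read
carries the barcode (the common 454/Ion layout; dual indexing is out of
scope) and the mate follows its assignment. Every read lands in exactly
one bin, so bin counts always sum to the input count.

Barcode tables are validated at load: equal-length barcodes closer than
`2 × max_mismatch` in Hamming distance draw a warning, because reads
between such a pair can only ever be unassigned.

## Adapter and primer trimming

The matcher is ungapped and k-mer seeded: every adapter k-mer
(`kmer = 10` by default) is looked up exactly in the read, each hit fixes
a candidate offset, and the full adapter is aligned ungapped at that
offset. All 3'-terminal placements of the adapter prefix of length ≥
`min_overlap` (default 5) are additionally evaluated, which covers
read-through into the adapter at the fragment end. A placement is accepted
when its mismatch count (N counts as mismatch) is at most
`ceiling(max_mismatch × aligned_length / adapter_length)` — the mismatch
budget scales with how much of the adapter is aligned. Fewest mismatches
wins; ties go to the leftmost placement, which removes the most sequence
and is therefore the conservative choice for a contaminant.

Seeding is exhaustive by pigeonhole whenever the adapter is at least
`(max_mismatch + 1) × kmer` long — true for full-length sequencing
adapters (~33 bp) at the defaults. Primers are shorter, so the 5'-anchor
rule does not rely on seeds at all: primer placements are evaluated
directly at read offsets 0–2, and a hit trims the 5' end through the match
end. Any adapter-like hit trims from the match start to the 3' end.
Features of the opposite orientation are searched as their reverse
complement and treated as 3' (read-through) matches. Matching is ungapped
by design: it keeps the brute-force all-offsets oracle exact, and indel
adapters are rare enough in these platforms that gap support would buy
little for the cost of an inexact contract.

Terminal N runs are removed (interior Ns are data). Low-quality ends are
trimmed with a terminal-window rule: while the mean quality of the
terminal window (size `min(window, length)`, default 5) is below `q_trim`
(default 20, the conventional 1%-error threshold), the terminal base is
dropped; the rule runs from the 3' end, then the 5' end, and the two
passes repeat to a fixed point. Iterating to the fixed point is what makes
the whole trimming cascade idempotent — a single 3'-then-5' sweep can
expose a newly-low end and would make "trim twice" differ from "trim
once". The full cascade (adapters → Ns → quality) likewise iterates until
the read stops shrinking, with adapter search capped at three rounds per
pass.

## Duplicate, contamination and threshold filtering

Duplicate removal is streaming with first-occurrence retention
(deterministic under any input order; best-quality retention would require
buffering the whole stream and is left as a documented alternative).
Three combinable definitions: `exact` (identical base string), `prefix`
(a read equal to the 5' prefix of an already-kept longer read — the
truncated-copy case), and `revcomp` (identical to the reverse complement
of a kept read). Duplicates are assessed per sample after demultiplexing,
because PCR duplicates are library-specific; for pairs the key is the
concatenation of both mates, and the pair is removed jointly.

"Contamination" screening is implemented as low-complexity filtering, the
operational capability of the tools this stage models; reference-based
contaminant screening (against, say, a host or vector database) is
explicitly out of scope. Two scores on a 0–100 scale over overlapping
3-mers of a length-`L` read:

* **DUST**: `100 × Σ_t c_t(c_t−1)/2 ÷ [(L−2)(L−3)/2]` — the fraction of
  identical 3-mer pairs relative to a homopolymer. Default: fail above 7.
* **Entropy**: Shannon entropy of the 3-mer distribution, normalised by
  `log(min(L−2, 64))` and scaled to 0–100. Default: fail below 30.

Reads shorter than 3 bases score 0 (no 3-mer evidence of repetitiveness).

Threshold filtering keeps a read iff its length is within
`[min_len, max_len]`, its mean quality is ≥ `min_mean_q`, and (for NGS)
its complexity is acceptable. `min_len` defaults to 50 for short reads and
100 for Sanger — below these lengths a clinical alignment is rarely
unambiguous. The first failing criterion is recorded per read, so the
pipeline can report exact removal accounting:
`reads_after + Σ removed-per-criterion = reads_before` for every sample.

Paired-end consistency: after per-side filtering, only pairs whose both
mates survive are written, in the forward stream's original order, so the
R1 and R2 output files always carry identical ordered identifier lists.
Mate identifiers are normalised by stripping `/1`, `/2` and space-delimited
(Casava-style) suffixes, the two dominant naming dialects.

## QC statistics and reports

Statistics are accumulated in a single pass: read/base counts,
per-position quality distribution (count, mean and nearest-rank quartiles
computed exactly from the per-position quality histogram — no streaming
approximation is needed because quality is bounded in 0–93), read-length
histogram, duplication levels (copy-number → distinct sequences),
overrepresented sequences (frequency > 0.1 % of reads, capped list), and
GC content. GC is `100 × (G+C+S) / (A+C+G+T+S+W)` per read — S is
definitionally G-or-C and W is A-or-T, other ambiguity codes and N carry
no GC information and are excluded from the denominator — averaged over
reads; an empty stream reports 0 with an explicit undefined flag.

The HTML report renders the before and after statistics verbatim (the
renderer re-derives nothing), with every numeric table also written as a
tab-separated sidecar. A sample whose reads were all removed renders with
an explicit "0 reads survived" marker. No output file contains a
timestamp, so byte-level comparison across runs is meaningful.

## Input contracts and configuration

The Target file is tab-separated with a mandatory unique `Patient_ID`;
platform is inferred from the first input file's detected format when not
given; unknown columns are carried verbatim into the summary table so
clinical annotations survive the run. The Adapter-Primer file is the
four-column (type, id, forward, reverse) table; its absence simply
disables feature trimming. The options file is flat `key = value` text
with dotted namespaces over a closed schema — an unknown key is fatal,
which catches typos that would otherwise silently run with defaults. The
effective configuration is echoed next to the outputs, and re-feeding the
echo reproduces the run bit-for-bit (a tested contract).

## The synthetic-data generator

All tests and the acceptance script run from generated data with planted,
machine-readable truth; nothing is downloaded. The generator emulates the
features the pipeline consumes:

* read lengths uniform on a configurable interval (default 80–120 bp for
  short-read simulations, 150–250 bp for traces);
* per-base quality falling linearly from Q35 at the 5' end to Q25 at the
  3' end with Gaussian noise (σ = 3), clamped to [2, 40] — the 3'-decay
  that motivates end trimming, at levels typical of a healthy short-read
  run;
* barcodes, primers and adapters planted outside-in
  (barcode + primer + insert + adapter) with recorded per-feature
  substitution counts (0–2, the tolerance the trimmer advertises);
* chromatograms as Gaussian peaks (σ = 2.5 samples) spaced every 12
  samples, primary height 1000, with configurable secondary peaks for
  ambiguity planting — the only trace properties the refinement rule
  consumes;
* flowgrams at 100 units per incorporated base on a repeated TACG cycle.

Two deliberate properties: the fixture writers construct the AB1/SCF/SFF
byte layouts directly and share no code with the readers, so round-trip
equality tests two independent codings of each format specification; and
inserts that would *accidentally* mimic a planted feature — an admissible
primer/adapter placement inside the insert, or a barcode-free read whose
5' end happens to spell a barcode — are regenerated at planting time,
because an exact-recovery check is only meaningful when the recorded
features are the unique admissible matches (at the default
`min_overlap = 5`, roughly 1–2 % of random inserts would otherwise end in
an adapter-prefix-like pentamer).

What the generator does **not** emulate — and what passing tests therefore
do not certify on real data: chromatogram noise, dye blobs and mobility
shifts; homopolymer flow-value noise (454/Ion's characteristic error
mode); sequence-dependent quality artifacts; indel sequencing errors in
adapters; dual-index barcode schemes.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive in all user-facing values and logs;
  internal offset arithmetic is 0-based half-open.
* Adapter-match ties resolve to fewest mismatches, then leftmost.
* Quartiles are nearest-rank (exact on the bounded quality histogram).
* Empty reads, empty streams, empty SFF files and zero-survivor samples
  are all defined states, not errors; a read trimmed to length 0 is later
  removed (and counted) by the length filter.
* An unreadable or corrupt input fails only its own sample; the cohort
  completes and the summary row records the failure.
* Problem sizes in the shipped tests (up to 1 000 records per format,
  10 000 reads for demultiplexing, 5 000 for filter accounting, a
  10-sample mixed cohort) were chosen to exercise the streaming paths at
  cohort-realistic scale while keeping the default suite fast.

## Known limitations

* The peak-ratio refinement rule is a transparent stand-in for
  trace-calibrated re-basecalling; its threshold is a design constant, not
  a fitted parameter.
* Ungapped adapter matching will not find indel-containing adapters.
* k-mer seeding can miss a *mismatched interior* placement of a feature
  shorter than `(max_mismatch + 1) × kmer`; 5'-anchored primers are
  exempt (anchored scan), and full-length adapters satisfy the bound.
* Reference-based contaminant screening, RNA-seq handling, colour-space
  reads, BAM/SAM input, and multi-read chromatogram containers are out of
  scope.
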