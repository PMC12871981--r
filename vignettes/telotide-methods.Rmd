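---
title: "Telomere length from capture-enriched nanopore reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Telomere length from capture-enriched nanopore reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telotide)
```

## The measurement problem

A human telomere is an array of the canonical repeat `GGTTAG`
(G-strand; `CTAACC` on the C-strand) up to tens of kilobases long,
preceded by chromosome-specific subtelomeric sequence. Enrichment
protocols ligate a short capture probe to the distal telomere end, so a
successfully captured read has the structure

```
5'-[subtelomere][variant repeat-rich region][invariant telomere][probe][barcode?]-3'
```

in G-strand orientation (C-strand reads are the reverse complement).
Estimating telomere length per read requires two positions: the distal
end (the probe) and the proximal boundary where subtelomere turns into
telomere. Neither is trivial on nanopore data: single-pass basecalls
carry substitutions and indels, and the subtelomere itself contains
telomere-like sequence.

## Telomere+1N content

Basecalling errors and genuine telomeric variants both perturb the
canonical repeat by about one edit. The package therefore scores
**telomere+1N** content: coverage by the canonical repeat or any string
within Levenshtein distance one of it (18 substitutions, 4 distinct
deletions, and the distinct single-base insertions, including at both
ends), on either strand. `telomere_motifs()` materializes this alphabet
(45 G-strand strings plus their reverse complements); mutant telomerase
repeat motifs can be added as a separate class that participates in all
scoring only when mutant mode is on.

Scanning (`scan_motifs()`) is greedy, left to right, non-overlapping.
At a position an exact canonical repeat wins outright; otherwise the
longest matching variant wins. Canonical precedence is not cosmetic:
inside a pure repeat array every repeat is also the prefix of a
one-base-insertion variant (`GGTTAGG`), so a longest-first rule would
classify invariant telomere as variant sequence and break canonical
repeat counting. Windowed content (`coverage_profile()`) is defined as
the *percentage of window bases covered* by telomere+1N hits, not a
motif count — fractional counts are ill-defined when variants are 5, 6,
or 7 bases long. Windows that would overrun the scanned region are
dropped rather than rescaled, so percentages at read ends are never
inflated. `N` bases match nothing.

## Pipeline stages and their parameters

Stages run in a fixed order; a read that fails is labelled with the
first stage that removed it, and the stage ledger satisfies
`entered(k+1) = passed(k)` throughout.

| stage      | rule (defaults)                                       |
|------------|-------------------------------------------------------|
| isolation  | ≥ 10 non-consecutive canonical repeats, either strand |
| strand     | G-fraction < 0.20 → C; > 0.80 → G; `[0.20, 0.80]` chimeric, removed |
| probe      | Hamming ≤ 2 errors (12-nt probe); first match after the 20th repeat |
| truncation | first 300 bases > 20% telomere+1N → removed           |
| boundary   | dual-threshold jumping window (below)                 |
| content    | telomere `[vrr_start, probe_start)` < 60% → removed   |
| upstream   | 2 kb before the boundary > 10% → removed              |

Notes on choices that were genuinely open:

* **Isolation counts canonical repeats only.** Variants at this stage
  would let noisy non-telomeric reads through; canonical-only counting
  is the stricter reading and what the strand classifier needs anyway.
* **"Non-consecutive"** means occurrences may lie anywhere in the read;
  the non-overlapping scan simply counts them.
* **The chimeric interval is closed** (`g = 0.20` and `g = 0.80` are
  removed): ambiguity is resolved toward removal. The other filters use
  strict inequalities ("more than 20%", "less than 60%", "more than
  10%"), so values exactly at a threshold pass.
* **Probe errors are substitutions only** (Hamming distance). This is
  reproducible, fast, and matches a "mismatch" budget; reads whose probe
  suffered an indel are lost at the probe stage (about 2.4% at 0.2%
  indel rate on a 12-mer), which the ledger makes visible. Longer
  probes need a proportionally larger budget; the scaling behavior is
  exercised in the test suite.
* **Tandem probes** (abnormal ligation products) are folded into a
  `tandem_count`; the telomere end is always the *first* probe start.
* **Demultiplexing** searches the 100 bp after the probe for each
  barcode; the unique best match assigns the sample and ties stay
  unassigned rather than guessing. Sheets are validated on load:
  barcodes must be pairwise more than `2 * barcode_max_errors`
  substitutions apart. With a sheet but no probe, the barcode position
  itself defines the telomere end; with neither, the read end does
  (flagged in `distal_end_source`).

## Boundary detection

The subtelomere-to-telomere transition announces itself as a sharp,
persistent rise of telomere+1N content. In a 100 bp window advanced in
15 bp steps (10 bp is available; 15 is the default as it is slightly
more precise and a third cheaper), the first window reaching the
**primary threshold of 60%** proposes the boundary: the first
telomere+1N hit starting at or after that window's start (hits
straddling the window's left edge are excluded).

The candidate is *invalidated* only when coverage later stays below the
**secondary threshold of 5%** for at least **15 consecutive windows**
(~225 bp at defaults). Short dips — diffuse variant blocks, local
basecalling wobble — are tolerated. After an invalidating run the scan
resumes beyond it, so a read whose telomere contains a long internal
basecalling artifact re-triggers downstream; the displaced call is then
caught by the upstream filter, which sees telomeric content where
subtelomere should be. This completion (re-trigger after an
invalidating run) is the package's own reading of the rescue rule,
needed so that genuine boundaries beyond a subtelomeric telomere-like
island can still be found. When a probe was located, windows are only
evaluated up to the probe start. The rescue run is counted in windows,
not bases.

Two reference strategies are retained for benchmarking:
`detect_vrr_start_single()` (the trigger threshold must hold for every
later window — defeated by any genuine dip) and
`detect_vrr_start_consecutive()` (first run of eight back-to-back
repeats — defeated by spacers and noise inside the variant region). On
simulated truth cohorts the dual-threshold detector has a mean absolute
error about an order of magnitude below the single threshold, which in
turn beats the consecutive-run baseline; the acceptance script
recomputes the exact figure.

One systematic effect is worth knowing: any base X extends a following
canonical repeat into the insertion variant `X+GGTTAG`, so on a read
whose variant region begins with a canonical repeat the called start is
one base upstream of the junction. Boundary errors therefore skew
toward slight telomere-length *overestimation*, and calls are accurate
to about a nucleotide on clean reads.

## The simulator and what it does (not) emulate

`sim_spec()` defaults describe the telomere-enrichment study
conditions: subtelomere 2–5 kb, VRR region 0.3–3 kb with a per-read
target telomere+1N coverage drawn from 80–100%, invariant telomere
uniform 1–8 kb (a lognormal family is available), a synthetic 12-nt
probe (`TACGACTGCAGT`, chosen ≥ 6 substitutions away from any telomeric
12-mer; real runs supply the enrichment oligo), an even C/G strand mix,
1% substitutions and 0.1% + 0.1% indels, and per-read baseline quality
Phred 12–20.

The subtelomere is random sequence *scrubbed* of every telomere+1N
match (`scrub_subtelomere()`, deterministic and idempotent), so the
recorded boundary is exact by construction and upstream signal can only
come from injected noise. Ground-truth coordinates are mapped through
the indel process and refer to the final read; the VRR region is built
from canonical/variant repeat units with short random spacers sized to
hit the target coverage.

Artifact classes mirror what real runs produce: proximally truncated
reads (start inside the VRR), tandem probes, probe-absent reads
(duplex-enrichment behavior), mid-telomere low-quality scrubbed blocks
(basecalling artifacts, Phred ≤ 9), subtelomeric telomere-like islands,
and chimeric reads joining opposite-strand telomeres.

What the simulator does *not* model: raw-signal (squiggle) behavior,
basecaller-specific artifact sequence composition (artifact blocks are
scrubbed random sequence with low quality), homopolymer-biased error
profiles, chromosome-arm-specific subtelomere structure, and real
subtelomeric repeat families. Passing tests on simulation therefore
demonstrate the algorithmic contract — stage attribution, boundary
accuracy under substitution/indel noise, rate recovery — not
performance on any particular basecaller's output.

## Problem sizes used in validation

The boundary-accuracy experiment uses a 400-read cohort at the default
study conditions (the acceptance script regenerates it from a
command-line seed). Stage-attribution checks use 150–300 read cohorts;
these are generated noise-free so each injected artifact class maps
one-to-one to its removal stage — with noise on, probe-stage removals
would conflate probe-absent artifacts with indel-corrupted probes.
Kernel-equivalence properties (scanning, windowed coverage, fuzzy
search, run finding) are checked exhaustively against brute-force
oracles on instances up to 200 bp.

## Degenerate inputs and numerical conventions

* Reads shorter than one window produce a flagged, truncated coverage
  profile and no boundary call (reason recorded).
* A boundary at the very start of a read has no upstream context and
  passes the upstream filter; the truncation filter already guards
  reads that begin in repeats.
* Empty intervals yield `NA` coverage; zero canonical hits yield the
  `non_telomeric` strand verdict.
* In-memory coordinates are 1-based closed (R convention); every file
  format writes 0-based half-open positions, stated in the file
  headers, so `telomere_length = probe_start − vrr_start` in either
  convention.
* Reverse complementing a read also reverses its quality string.
* The per-arm uniform expectation is returned exactly as `100/92` (so
  `92 × value = 100`); the conventional display truncates to `1.08`.

## Known limitations

* Hamming-only probe matching loses reads whose probe spans an indel;
  an alignment-based (edit-distance) matcher would recover them at a
  specificity and runtime cost.
* Organisms with heterogeneous telomeric repeat units need a different
  motif model; the edit-distance-1 neighborhood of a single canonical
  repeat is a vertebrate-style assumption.
* The strand classifier assumes repeat content dominates the telomeric
  region; reads that are almost entirely subtelomere can reach the
  chimeric band and be removed even when genuine.
* Telomere-length accuracy is bounded by the probe position: without a
  probe (or barcode) the read end stands in, which overestimates length
  by any adapter remnant present.
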