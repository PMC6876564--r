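---
title: "Measuring poly(A) tail length and composition from CCS reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring poly(A) tail length and composition from CCS reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccstail)
```

## The measurement problem

Short-read platforms cannot read through long homopolymers, so the
length and base composition of mRNA poly(A) tails are invisible to
conventional RNA-seq. Single-molecule circular consensus sequencing
(CCS) solves both problems at once: a circularized full-length cDNA that
retains its poly(A) stretch is read many times ("passes"), and the
per-molecule consensus is accurate enough to count individual bases
inside a homopolymer. `ccstail` implements the downstream computation
for such libraries: demultiplexing and adapter hygiene, tail extraction
from genome alignments, quantification of non-adenosine (U, G, C)
residues inside tail bodies, spike-in calibration, gene assignment, and
polyadenylation-site clustering — plus a synthetic-read generator that
makes every stage testable against known ground truth.

Consensus accuracy is governed by the pass count, so a single pass
threshold (default `min_passes = 10`) gates both tail length and
composition calling. Raising the threshold only ever removes reads; it
is applied once, at tail calling, and not re-applied downstream.

## Demultiplexing and read cleaning

Each sample is identified by a 22-nt probe: a 16-nt barcode followed by
the first 6 nt of the template-switching oligo. Probes are matched
semi-globally (infix) against each read and its reverse complement with
a Levenshtein tolerance of `max_edits = 2`. The tolerance counts
substitutions and indels together; a combined bound is the standard
reading of "mismatches or indels" and is strictly more conservative
than two of each. Among overlapping candidate placements the lowest-edit
one wins, with ties broken to the leftmost start and then the shortest
span — a fixed, documented order so that demultiplexing is
deterministic.

The matcher is a bit-parallel Myers scan (the probe fits one machine
word) followed by a small dynamic program at candidate end columns to
recover concrete placements; `N` bases never match anything. Probe sets
whose minimum pairwise edit distance is `<= 2 * max_edits` cannot be
distinguished at the stated tolerance, so `probe_set()` warns about
them. Reads matching two distinct barcodes are discarded as ambiguous;
a read whose single probe matches on both strands has no defined
orientation and is likewise set aside (`orientation_conflict`) rather
than guessed.

Cleaning then proceeds on the oriented read (tail at the 3' end, the
reverse complement of the probe terminal): the 3' adapter is trimmed at
the probe match; concatemers — probe or 5'-primer copies in the read
interior — are resolved by keeping the 3'-most unit, dropping each
interior match and everything 5' of it; and the 5' cDNA primer is
removed when present within the first 50 nt (its absence is tolerated).
Retained sequences shorter than `min_len = 50` nt are set aside. Every
step only removes sequence; no base is ever introduced.

## Tail extraction from alignments

Alignment is an explicit external step (a splice-aware long-read
aligner with secondary alignments suppressed); the package consumes the
resulting SAM/BAM and never produces alignments itself. Secondary and
supplementary records are rejected, never silently used.

In a genome alignment of a clean read, the poly(A) tail cannot align
and therefore appears as the clipped segment at the read's 3' end: the
right-hand clip of a forward-strand record, the left-hand clip of a
reverse-strand record (SAM stores minus-strand reads
reverse-complemented). The clip is recovered from the clean read
sequence by length, which makes soft and hard clips equivalent. A clip
is accepted as a poly(A) tail only if all three criteria hold:

1. length at least 15 nt,
2. at least five consecutive adenosines,
3. fewer than 20 non-A residues, making up less than 50% of the clip.

`N` counts as non-A. The first failed criterion is reported as the
rejection reason. Two defensive choices go beyond the criteria: a read
whose 5'-end clip would itself pass all three tests is rejected as
suspicious (an un-trimmed adapter can masquerade as a tail), and a
CIGAR whose query length disagrees with the supplied read sequence is
refused outright. No upper cap is placed on tail length.

Per-gene tail length is summarised by the geometric mean,
`exp(mean(log(length)))`, because per-gene tail lengths are
lognormal-like; the arithmetic mean would be dominated by the long
tail of the distribution. Genes need at least `min_reads = 3` accepted
tails for a summary (10 for between-replicate correlations, where
per-gene estimates must be stable).

## Non-adenosine residues in tail bodies

G, C, and U (read as T in consensus space) are counted per tail;
per-transcript ratios divide by tail length, and the gene-level ratio
pools counts (total non-A over total bases) rather than averaging
per-read ratios, so short tails do not dominate. The run spectrum
counts maximal same-base non-A runs by length (1, 2, 3, 4+); a `GGC`
stretch is one G-run of two plus one C-run of one, which keeps the
weighted sum of the spectrum equal to the total non-A count.

"Internal" non-A fractions are reported twice: raw (any non-A
anywhere) and with the maximal terminal non-A run stripped first.
Terminal residues are partially lost to adapter pairing during library
construction and are therefore the less reliable signal; both variants
are emitted because the stripped definition is a package choice, not a
universal convention. Positional profiles use `k = 20` equal
relative-position bins (tails vary in length), with an absolute
5'-anchored profile emitted alongside since the two views answer
different questions.

The oligo(dT)-T30VN anchoring analysis provides orthogonal,
base-pairing evidence for internal non-A residues in conventional
libraries: reads where the RT primer's VN end annealed within the tail
body retain genuine tail sequence (one or more A, then the 1-2
anchoring non-A bases) between the 3'-UTR end and the long terminal
A-stretch. The terminal A-run threshold is 25 nt — the T30 complement
minus tolerance; no canonical value exists, so it is a parameter.
Junctions that fit neither model (more than two non-A bases between
tail A's and the terminal run) are reported as non-classifiable rather
than forced into a category.

## Spike-in calibration

Synthetic barcoded cDNAs with defined tails of 10, 30, 50, 70, and
100 nt calibrate the measurement. The structural parser requires every
feature — 5' primer, barcode, reporter body, tail, 3' primer — in
order, using 30-nt body anchors at `<= 3` edits and primers at `<= 2`;
everything between the reporter body and the 3' primer is the measured
tail. No minimum clip length applies here, so the 10-nt design is
measurable. Each design has one homogeneous designed length, so the
per-design summary uses the arithmetic mean. The shipped design
(`default_spikein_design()`) is a synthetic stand-in — the original
reporter and primer sequences are not distributed with the package —
with 10-nt barcodes at pairwise edit distance above 4 and a 600-nt
body; it is data for tests and calibration exercises, not a claim about
any particular construct.

## Gene assignment and polyadenylation sites

Exons are merged per gene (duplicates removed) from the GTF, and an
alignment's reference-consuming blocks (CIGAR M/=/X/D) are intersected
with them: exactly one overlapping gene assigns the read, two or more
discard it, zero leaves it unassigned. Coordinates are 0-based
half-open internally and converted only at the GTF/SAM/BED boundaries.

Cleavage sites are the strand-aware genomic 3' ends of tail-bearing
reads. Sites are called by single-linkage clustering within a 24-nt
window — the typical cleavage-heterogeneity scale — with at least 2
supporting reads, positioned at the modal end (ties resolved toward
the most distal position, which is robust to ragged cleavage). Genes
are classed by site count with the convention that two sites equal one
alternative-polyadenylation event. This clustering is a deliberately
simple, documented substitute for heavier APA pipelines; comparisons
with published APA catalogues should be read as qualitative.
Isoform-level grouping uses exact intron-chain equality.

## The synthetic generator

`generate_dataset()` emulates the library: each read is
`5' primer + cDNA + tail + revcomp(probe)`, over a toy genome of ~20
genes of 0.5-1.5 kb with 1-4 exons each (small enough that a full run
takes seconds). Per-gene tail lengths are lognormal with per-gene
meanlog drawn from `log(40)`-`log(120)` and sdlog 0.25 — geometric-mean
tails of roughly 40-120 nt, the scale observed in transcriptionally
quiescent oocytes. Internal modifications are injected at `mod_rate =
0.007` per base (the bulk non-A frequency scale in tail bodies) with a
5'-biased exponential positional weight normalised so the mean rate is
exact; an optional secondary 3' G mode and terminal modifications are
available. Pass numbers are Poisson with mean 30, concatemers and
sequencing errors are off by default, and every draw flows through R's
seeded RNG, so a seed fully determines the output.

Alignments are emitted by construction, not by running an aligner:
each clean read is placed on the toy genome with its tail as the
3'-terminal soft clip, so tests have exact coordinate truth and no
external binary dependency. This forces one honest asymmetry in the
error model: substitution errors may fall anywhere, but indel errors
are confined to the tail, because an indel in the templated portion
would invalidate the constructed CIGAR. Measured tail lengths therefore
degrade with the error rate exactly as a real aligner's soft clips
would, while alignments stay exact.

What the generator does not emulate: pass-number-dependent error
profiles, polymerase homopolymer slippage, reverse-transcription
artifacts, expression-level variation between genes, or annotation
imperfections. Passing recovery tests on synthetic data therefore shows
the *computation* is correct — boundaries exact, estimators unbiased,
clustering faithful — not that any particular biological dataset will
be free of those upstream effects.

## Numerical choices and degenerate inputs

- Probe/anchor tie-breaks: lowest edits, then leftmost, then shortest.
- Histogram bins are left-closed, right-open, 20-nt wide; the final bin
  absorbs the maximum so counts always sum to *n*. The long-tail view
  restricts to tails above 200 nt.
- The geometric mean of an empty set is an error, not `NA`; gene
  summaries simply omit genes below the read floor.
- Empty reference site sets yield an overlap fraction of 0 with a
  warning; a single shared gene yields an `NA` correlation.
- Reads without pass information default to `num_passes = 1` with a
  warning (and are then removed by any pass filter of 2 or more) rather
  than being dropped — defaulting is visible, dropping is silent.
- In the end-to-end recovery test, per-gene geometric means are
  compared to `exp(meanlog)` within `3*sdlog/sqrt(n)` on the log scale,
  plus a 0.01 allowance for the discretisation of simulated lengths to
  integers.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_genes = 10, reads_per_sample = 200,
                  samples = c("repA", "repB"))
sim <- generate_dataset(cfg, out_dir = "sim")
manifest <- run_pipeline(reads = sim$files[["reads"]],
                         barcodes = sim$files[["barcodes"]],
                         alignments = sim$files[["sam"]],
                         gtf = sim$files[["gtf"]],
                         out_dir = "out",
                         ref_bed = sim$files[["sites"]])
manifest
```

## Known limitations

- Demultiplexing guarantees hold only when probe sets keep pairwise
  edit distance above `2 * max_edits`; the constructor warns, but
  closely spaced barcodes remain the user's responsibility.
- The VN-anchoring classifier assumes the 3'-UTR end position is known
  from an alignment; mis-annotated UTR ends shift model-a/model-b
  calls.
- Site clustering has no statistical model of cleavage noise; a window
  is a window. Genes whose true sites are closer than the window merge.
- The spike-in parser assumes a shared reporter body across designs;
  pools with heterogeneous bodies need one design object per body.
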