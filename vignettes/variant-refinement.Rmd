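---
title: "Read-level variant refinement: metrics, tags, v-score and the boosted refiner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-level variant refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vartag)
```

## The problem

Short-read variant callers are sensitive but not specific: a sizable
fraction of candidate calls are alignment or library artifacts. The
traditional remedy is manual review in a genome browser, where a reviewer
recognises a small vocabulary of failure modes — supporters piled at read
ends, one-strand-only support, identical duplicate stacks, low mapping
quality, secondary mismatches travelling with the allele, repeat slippage,
support confined to the overlap of short fragments, and (for somatic
calls) evidence in the matched normal. `vartag` encodes that vocabulary as
quantitative read-level metrics, categorical tags, and one weighted score,
so review becomes reproducible and automatic.

## Evidence extraction

For each candidate (SNV, insertion or deletion, normalized to left-aligned
minimal representation), the covering reads are retrieved from the
coordinate-sorted indexed BAM through the index (`Rsamtools::scanBam` with
a region query), which makes per-variant retrieval logarithmic in track
size. Duplicate, secondary, supplementary and unmapped records are
excluded by default — this matches what a reviewer sees in a default
browser track, and is configurable off.

Support is decided on the CIGAR: an SNV is supported when the base aligned
to the locus equals the alternate allele; an insertion when an insertion
of exactly the inserted sequence is anchored at the locus; a deletion when
a deletion of exactly the deleted length starts one base later. A read
whose aligned span includes the locus without carrying the allele covers
only; a read whose deletion spans the locus covers but supports nothing.

Distances to the read head and end are measured in aligned-reference space
from the first and last aligned (non-clipped) base: soft clips are
invisible to a reviewer's sense of "near the end", so they do not count.
Mate geometry is taken from the mate position, with the mate span
approximated by the read length; support lying where both mates overlap is
what the short-insert metric counts, while its denominator is all paired
supporters with a mapped mate.

Secondary mismatches are cataloged as (position, base) substitutions
within ±10 bp of the locus, excluding the locus itself. Indel alleles at
*other* positions are not cataloged as mismatches; they are captured
separately by the adjacent-indel metrics. This keeps the mismatch-based
metrics (`mm`, `hdr`) specific to substitution noise.

## The metrics and their conventions

All rate metrics divide by the supporter count `d_m` and are 0 when there
are no supporters (with a warning); coverage risks use
`1 - min(thr, d)/thr` so they are 0 exactly when coverage meets the
requirement. Conventions that the formulas alone do not fix:

* **"under threshold" for distances** is inclusive: a supporter whose head
  is exactly 5 bp from the locus counts as near. For MAPQ it is strict:
  quality exactly 10 is not low. Both are configurable
  (`vartag_config(near_dist =, mapq_thr =)`); the boundary cases are
  unit-tested both ways.
* **Adjacent-indel events are counted per supporting read** (a read
  contributes at most one insertion event and one deletion event), which
  keeps `ni` and `nd` within [0, 1] — consistent with their denominators.
* **The mismatch window count `n`** is the number of reference positions
  within 10 bp upstream and downstream of the locus, excluding the locus:
  20 on a full window, fewer at contig edges. Mismatch frequency is
  measured against total coverage `d`.
* **The high-discrepancy score** computes `HR = 2h/(d_m + d_i)` for every
  cataloged mismatch that co-occurs with the candidate on at least one
  supporting read. When the maximal HR reaches the recurrence threshold
  (0.9), `hdr` is the sum of the HRs **at or above the threshold**, not of
  all HRs: summing sub-threshold ratios would let many unlinked mismatches
  inflate the score and defeat the tag's intent. Two fully linked
  mismatches therefore give `hdr = 2`, the branch where the score exceeds 1.
* **Other-allele reads (`d_mv`)** are counted as reads, not distinct
  alleles, because the companion tag rule requires `d_mv ≥ 2` reads; the
  distinct-allele count is recorded alongside for diagnostics. Reads whose
  deletion spans the locus present no attributable allele and are not
  counted.
* **Repeat context**: a tandem tract qualifies with unit length 1–5 and at
  least 4 copies (5 for homopolymers), within ±10 bp; the flag `r` fires
  when a qualifying tract contains or lies within 5 bp of the locus. The
  repeat-insertion flag `ri` accepts any cyclic rotation of the minimal
  unit, since left-alignment makes the rotation arbitrary. The large
  duplicative insertion flag `li` fires at 20 bp or more matching the
  adjacent reference on either side.
* **Base quality is not used anywhere.** The metric set is purely
  positional/alignment-based; a base-quality filter would be a natural
  configurable extension.

In somatic mode the normal track is summarised first: every non-reference
base allele with at least two supporting normal reads is scored with the
germline metric vector (using the normal-track coverage requirement
`thr_n`), and alleles scoring at or below 3.5 are declared germline. The
cutoff sits at the midpoint of the 3–4 band where the score threshold is
empirically robust; it is configurable. Detected germline alleles are
excluded from the tumor-track `d_mv`, and two further metrics are added:
`nvaf = d_n/d_normal` and `lncr = 1 - min(thr_n, d_normal)/thr_n`.
Germline-allele detection considers base alleles only; indel alleles in
the normal are a documented limitation.

## Tags and the v-score

The 19 tags apply fixed predicates to the metric vector (`LC`: `lcr > 0`;
`LVF`: `vafr ≥ 1 − thr_vaf`; `LM`: `lm ≥ 0.2` and `d_l ≥ 2`; `MM`:
`mm ≥ 1`; `HDR`: `hdr ≥ 1`; `HE`/`EN`/`NI`/`ND`/`D`/`SSE`/`SI`: rate
≥ 0.9; `RR`/`RI`/`AO`: flag = 1; `NCN`: `lncr = 1`; `LCN`:
`0 < lncr < 1`; `VN`: see below). `RR` is a prerequisite of `RI` and is
always emitted with it. Somatic-only tags are suppressed in germline mode.

The published form of the tumor-in-normal rule, `nvaf ≥ 0.1 × thr` with
`thr` a read count, is dimensionally inconsistent (a frequency compared
against a tenth of a read count would require `nvaf ≥ 1.5` under typical
settings). We read it as `nvaf ≥ 0.1 × thr_vaf` together with at least two
supporting normal reads — "the variant occurs in the normal track" — and
keep the literal reading selectable via `vartag_config(vn_rule =
"literal")`.

The v-score is linear: `v = Σ w_i x_i` with level weights 3
(`lcr, vafr, lm, ni, nd`), 2 (`lncr, mv, hdr`) and 1 (the rest; the level-1
weight is fixed at 1). Weights are configurable per application
(`vartag_weights(hdr = 3)`). Low scores indicate likely true variants, so
the threshold sweep classifies `vscore < t` as positive, strict inequality,
with ties on F_β broken toward the smallest threshold; thresholds run from
0 to the maximal observed score in 0.1 steps. β defaults to 0.3
(precision-leaning). Degenerate sweeps (single-class truth) report 0 for
the undefined rate with a warning rather than failing.

## The refinement classifier

All metrics form the feature matrix (fixed canonical column order,
embedded in the fitted object; prediction refuses a mismatched schema).
The booster uses the binary-logistic objective; the grid search covers
learning rate {0.01, 0.05, 0.1} × gamma {0.1, 1, 10} × depth {3, 6, 9} —
27 points — each evaluated by 10-fold cross-validated mean AUC with seeded
fold assignment, and the winner is refit on the full data. The number of
boosting rounds is fixed (default 100) rather than tuned, and the CV
selection metric is AUC; both choices are ours where the protocol leaves
them open. Training is deterministic given the seed (single-threaded
boosting). AUC is computed by the Mann–Whitney rank statistic with midrank
ties, cross-checked in the test suite against both exhaustive pair
counting and `pROC`.

## The synthetic pileup generator

The generator emulates 100 bp paired-end sequencing with ~300 ± 30 bp
fragments over small random contigs (GC 0.5, homopolymer runs capped at 3
so repeat context appears only where requested). Each artifact signature
manipulates exactly the supporting reads that carry it — e.g. `near_head`
places the locus within 5 bp of the aligned start of the affected
supporters, `short_insert_overlap` shrinks the fragment to 150 bp so both
mates cover the locus, `linked_mismatch` adds one or two substitutions
that travel with the allele — while everything else stays clean: mid-read
support, MAPQ 60, balanced strands, distinct coordinates, reference-exact
sequence. Requested depth and allele fraction are realized within one
read. Truth labels follow the simulation convention that `none` means a
true variant and every artifact signature means a false one; that is a
convention for supervised evaluation, not a biological claim.

What the generator does **not** emulate: sequencing error (reads are
error-free outside the injected signatures), base-quality structure,
indel-realignment ambiguity, multi-nucleotide substitution haplotypes, GC
or mappability bias, and structural variation. Passing the closed-loop
tests therefore shows that the metrics, tags and score respond correctly
to isolated, cleanly injected artifact modes — not that the default
thresholds are optimal on any particular real library.

## Problem sizes and numerical choices

The test suite and acceptance script run entirely on simulated data at
desk scale, chosen to exercise every code path: 500 randomized ≤ 30-read
pileups for oracle equivalence and the range law, 19 signature closed
loops at super- and sub-threshold intensity, a 150-variant dataset (depth
25) for the threshold sweep, a 200-variant dataset for the
parallel-determinism check, and 27-point grid searches on a few hundred
synthetic metric vectors with 30–40 boosting rounds. Published AUCs on
benchmark genomes require the external benchmark datasets and are out of
scope; the classifier claim kept here is directional — on labels that are
a noisy monotone function of a few equally-weighted metrics, the learned
model outranks the fixed-weight score on held-out data.

Degenerate inputs are defined, not fatal: an empty pileup scores maximal
coverage risks and zero rates; a locus with no supporters scores zero
rates with a warning; `si` is 0 for single-end data; an empty VCF produces
valid empty outputs. Per-variant scoring is independent of worker count
and processing order, and output files are byte-identical across
parallelism levels.

## Known limitations

* The mate span is inferred from the mate start plus this read's length;
  mates of different length (trimming) shift the overlap boundary slightly.
* MNP/complex substitutions are not modeled as candidates; they surface as
  linked mismatches (`HDR`), mirroring their appearance in review.
* CRAM input, realignment and phasing are out of scope.
* Metric weights are fixed per run; learning them from labeled data is the
  natural next step and is deliberately not attempted here.
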