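---
title: "Methods: footprint-based translation efficiency and cRACE tail calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: footprint-based translation efficiency and cRACE tail calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboTails)
```

riboTails implements two analysis tracks that together characterize a
translational phenotype: (i) ribosome-profiling arithmetic — footprint
filtering, A-site inference, codon occupancy, metagene profiles and
translation-efficiency (TE) calling — aimed at detecting gene-set-specific
changes such as 5'-CDS ribosome stalling on ER-targeted (signal-peptide)
mRNAs; and (ii) exact 3'-end reconstruction of a small RNA (such as the
SRP's 7SL RNA) from circularization-RACE reads, with oligo(U) tail calling
and a logistic model of uridylation probability against 3' truncation.
This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## Ribosome-profiling track

### Footprint filtering and A-site inference

A ribosome-protected fragment (RPF) is retained when it is uniquely
mapped, 28–31 nt long, and its A site — taken at a fixed offset of 15 nt
from the fragment's 5' end — falls inside the CDS in the zero reading
frame. The same single offset is used for all four retained lengths;
per-length offset calibration is deliberately out of scope. Filtering is
strictly separated from ingestion: alignment readers never drop reads by
length or frame, so every filter is testable in isolation, and
`filter_rpfs()` reports per-rule rejection counts. All coordinates are
0-based, half-open in transcript space; SAM input is converted at the
boundary (`POS - 1`).

### Codon occupancy with basal normalization

The raw occupancy of an A-site event is the footprint count at its codon
position. Because genes differ enormously in expression, each event is
normalized by its *basal* occupancy: the mean of the raw counts at the
+1, +2 and +3 codons downstream on the same gene. The normalized
occupancy of a codon species is the mean of these per-event ratios over
all events decoding it. Under globally uniform coverage every codon's
occupancy is exactly 1, a self-normalization identity the test suite
asserts to 1e-9. Events on the last three CDS codons (no +3 context) or
with a zero basal are excluded and counted, never divided. Note the
estimator is event-weighted, so positions with more footprints weigh
more; under sparse counts this inflates occupancies slightly above 1 on
average (a property of the ratio estimator, not a bug), which is why
occupancy should be compared between codons or conditions rather than
read as an absolute rate.

### Metagene profiles

Each CDS is divided into 50 equal bins; an event at codon `i` of an
`L`-codon CDS falls in bin `floor(50 i / L)`. Per-gene binned counts are
divided by the gene's total footprint count — each per-gene profile sums
to exactly 1 — and the profile is the unweighted mean over genes, so a
handful of very deep genes cannot dominate the shape. Genes with fewer
than `min_rpf` (default 32) footprints are dropped; genes shorter than 50
codons are allowed but flagged, since their bins hold unequal numbers of
codons. Equal gene weighting was a genuinely open choice; we prefer it
because the alternative (read weighting) makes the profile an
expression-weighted average that a single outlier gene can dominate.

### Translation efficiency and differential calls

TE is footprint abundance on the CDS divided by mRNA abundance. Counts
are scaled to counts-per-million (CPM) within each library (totals taken
over testable genes), a pseudocount of 0.5 stabilizes ratios at low
counts, replicate TEs are combined by geometric mean per condition, and
the knockout-vs-control contrast is `log2_te_ratio`. A gene is testable
when its mRNA count is at least 10 in every mRNA library and its RPF
count at least 10 in at least one library; non-testable genes are
reported but never called. Differential translation uses the plain
2-fold rule: `down` iff `log2_te_ratio <= -1`, `up` iff `>= +1`. The
pseudocount, the count floor and the geometric-mean combination are
stability choices; CPM (rather than raw counts) makes replicates of
different depth comparable. No shrinkage-based Wald testing is layered on
top: the fold-change rule *is* the caller.

### Downstream statistics

Enrichment of signal-peptide / transmembrane annotation among `down` (or
`up`) calls is a two-sided Fisher's exact test on a 2×2 table whose
background is the *testable* genes only — genes that could never be
called must not pad the margins. The two-sided p-value follows the
point-probability convention (sum of hypergeometric probabilities not
exceeding that of the observed table, with the customary `1 + 1e-7`
tie tolerance); the reported odds ratio is the sample odds ratio
`ad/bc`. Codon usage between two gene sets is compared on CDS codon
frequencies (stop codons excluded) with a per-codon two-proportion
chi-squared test and Benjamini–Hochberg adjustment across the 61 sense
codons; occupancy-based comparison is possible via the occupancy table
but is not the primary statistic.

## cRACE track

### Junction detection and the greedy templated-first rule

A cRACE read spans the ligation junction:
`[3'-terminal reference segment][non-templated tail][reference 5' prefix]`.
`locate_junction()` finds the unique exact occurrence of the reference 5'
prefix (default 20 nt) in the read; the preceding segment is seeded onto
the mature sequence with its first 12 nt (`min_anchor`) and the exact
match is extended maximally. Ambiguity — no anchor, multiple anchors, or
two equally long placements — discards the read with a reason code;
nothing is ever guessed. When the matched terminus reaches the canonical
3' end, `call_tail()` continues consuming read bases that match the
*genomic* sequence downstream (for a Pol III transcript, a templated 4-U
terminator). Only what remains is the non-templated tail, reported in
the RNA alphabet, and a read is called uridylated iff that tail contains
at least five consecutive U. The templated-first rule is forced by the
biology: a read ending in exactly four U's at the canonical end is
read-through, not uridylation, and the ≥5-U criterion is what separates
the two. The rule makes uridylation calls conservative — a templated U
can never be credited to a tail. For comparison, every call also
carries `raw_segment_uridylated`, the literal criterion applied to the
whole pre-anchor read segment with templated bases included; the two
verdicts are reported side by side, never merged. Anchor matching is
exact by default with an optional one-substitution tolerance
(`max_anchor_mismatch = 1`).

### Logistic model of uridylation versus truncation

With `x` the 3' truncation in nucleotides (`x = -end_offset`; genomic
extensions enter as negative truncation so all molecules sit on one
signed axis), the model is `P(uridylated) = logistic(b0 + b1 x)`,
fitted by Newton–Raphson on the log-likelihood with a 1e-8 tolerance on
the gradient norm and at most 50 iterations; standard errors come from
the observed information. Complete or quasi-separation (outcomes
perfectly ordered by `x`) makes the likelihood monotone and the
coefficients unbounded; it is detected up front and returned as a flag
rather than an error. A `truncation_only` switch restricts the fit to
non-extended reads for sensitivity analysis; the signed axis is the
default.

## What the synthetic generators emulate

The generators exist so every stage has parameter-recovery tests with
known ground truth; their defaults are the study conditions the test
suite and the acceptance script run under.

**Ribo-seq generator.** 2,000 genes with CDS lengths uniform on 100–400
codons, log-normal mRNA abundances (sdlog 1) shared between conditions
(the modeled knockout does not change steady-state mRNA), log-normal
null TE ratios (sdlog 0.15, a modest gene-level variability), 20 genes
planted 2.5-fold down (ratio 0.4, safely past the 2-fold rule's
boundary), and — on signal-peptide genes in the knockout — a stall
modeled as a 5× footprint-density multiplier over the first 25 codons,
renormalized within the gene so totals reflect TE only. Libraries hold
2M reads; fragment lengths follow a 28–31 distribution with 5% decoy
lengths outside the window, 5' ends are jittered off-frame with
probability 0.1, and 2% of reads are flagged multimapping, so the
length, frame and uniqueness filters all have real work to do. What is
*not* emulated: sequence-dependent ligation/PCR bias, rRNA/tRNA
contamination (removed upstream in real pipelines), positional ramps
other than the planted stall, and biological replicate variability
beyond counting noise. Passing tests therefore demonstrate correct
arithmetic and calibrated calling under counting noise — not robustness
to every artifact of real libraries.

**cRACE generator.** A synthetic ~300-nt reference (random sequence, no
real RNA embedded) whose genomic extension begins with the templated
4-U terminator. 3' termini mix geometric truncation (p = 0.08, capped
at 60 nt, so most reads end before the canonical end) with 10%
terminator read-through; uridylation is Bernoulli with
`logistic(-3 + 0.25 x)`; uridylated tails are 5 + geometric U's,
non-uridylated reads carry a short (≤4 nt) U tail 30% of the time.
Termini are sampled at *tail-stable* positions only: a sampled terminus
whose next templated base is U slides to the end of that templated
U-run. This is an identifiability choice — a U tail drawn immediately
upstream of templated U's is partially indistinguishable from
read-through, so without it the generative truncation and the
observable truncation would systematically differ and the logistic
slope could not be recovered unbiasedly by *any* caller. The greedy
caller itself is unchanged and is tested separately on absorbable
fixtures. An optional uniform substitution rate stresses junction
detection; the empirical truncation spectrum of any real RNA is a
user-supplied matter, not asserted here.

## Numerical and degenerate-input conventions

* Ties in junction placement or anchor occurrence discard the read —
  never a guess.
* Fisher tables with a zero margin return p = 1 with a `degenerate`
  flag; infinite/zero sample odds ratios are flagged, not mangled.
* Occupancy events with zero basal are excluded and counted.
* Metagene bin mapping uses `floor` with no interpolation; fractional
  codon-per-bin effects for short genes are flagged rather than hidden.
* The logistic fit refuses single-outcome data (< 10 calls or all one
  class) and flags separation instead of iterating to overflow.
* Every generator is a pure function of (config, seed); the RNG state
  of the caller is saved and restored.

## Problem sizes

The test suite and the acceptance script run the ribo track at 2,000
genes × 2M reads per library (three independent studies pooled for the
TE sensitivity/FDR estimate), the metagene contrast at 300 genes × 1M
reads, the Fisher check over all 162,315 tables with margins ≤ 30, and
the cRACE track at 1,000 reads per replicate with 100–200 replicates
for coverage and null calibration. These sizes give the stochastic
checks comfortable margins (e.g. binomial SE ≈ 2% on a 100-replicate
coverage estimate) while keeping a full run in minutes on one core.

## Known limitations

* One fixed A-site offset for all lengths; no P-site analysis, no uORF
  handling.
* TE calling is threshold-based by design; it inherits the 2-fold
  rule's insensitivity near the boundary (a true ratio of exactly 0.5
  is recovered about half the time — hence the planted ratio 0.4 in
  recovery tests).
* The occupancy estimator is event-weighted (see above).
* Junction detection is exact-match; one-mismatch anchor tolerance is
  available but alignment with indels is out of scope, so highly
  error-prone reads are discarded rather than rescued.
* The enrichment background is testable genes; if testability itself
  correlates with the annotation, the odds ratio is conditional on
  that.
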