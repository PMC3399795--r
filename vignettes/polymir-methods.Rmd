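---
title: "Methods: small RNA profiles and miRNA additivity in hybrid polyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA profiles and miRNA additivity in hybrid polyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polymir)
```

## The design and the question

`polymir` analyses small RNA-seq libraries from a hybrid polyploid
complex in which individuals carry different dosages of two parental
genomes, P and A: parental-type diploids PP and AA, the diploid hybrid
PA, and the triploid hybrid PAA (one P, two A copies). The question the
workflow answers is whether miRNA expression in the hybrids is
*additive* — equal to the dosage-weighted average of the parental-type
profiles — or shifted, which would point to an active regulatory
response to hybridization or to the extra genome copy.

A `genome_composition` records the dosage map (e.g. `P:1, A:2` for PAA)
and drives every dosage-weighted computation downstream.

## From reads to profiles

**Filtering.** Small-RNA reads are normalized to upper-case DNA (U to
T), 3'-adapter-trimmed (longest exact prefix of the adapter, minimum
overlap 6 nt), and kept when they contain no N, have mean Phred quality
of at least 20, and are 14–30 nt long after trimming. The length window
is the defining property of a small-RNA library; the other rules are
standard practice, since raw-quality criteria differ between
base-calling pipelines and cannot be recovered from a published summary.
The report of kept/discarded counts always conserves reads.

**Collapsing.** Clean reads are grouped into unique *tags*, each
carrying its total read count (`collapse_tags()`); all later stages work
on tags. Sequence comparison between libraries (`pairwise_shared()`,
`shared_matrix()`) is on unique sequences only — read counts play no
role there — and the single "percent common" per pair is the mean of the
two directional percentages, since a one-number-per-pair summary needs a
choice of denominator and the mean treats both libraries symmetrically.
Both directional values are always retained.

**Annotation.** Tags are matched exactly against the reference on both
strands (`map_tags()`, a preprocessed dictionary match; a mismatch
budget is available but defaults to 0 — at 14–30 nt and desk-scale
references, exact matching is the transparent choice and the analysis
consumes only category assignments, not alignment detail). Each mapped
tag receives exactly one category by pooling the categories of all
features overlapping any of its hits and taking the highest priority in
the order rRNA, tRNA, snRNA, snoRNA, mRNA (structural and housekeeping
classes), then miRNA, then repeat, exon, intron. Overlap means at least
one shared base; the hit strand must equal the feature strand for miRNA
(mature miRNAs are strand-defined) and is ignored for the other
categories. Ties within a category break to the lowest (sequence, start)
so output is deterministic. Mapped tags overlapping no feature are
"unannotated"; coordinates are 1-based closed throughout.

**Expression.** A miRNA's expression in a library is its read count
divided by the library's total miRNA reads, so each profile is a
proportion vector summing to 1. The comparative universe defaults to the
intersection of miRNAs detected in every library (a "conserved miRNA"
set); profiles are *not* renormalized after restriction to that universe
— the denominator stays the library's total miRNA reads, matching the
definition above — though `renormalize = TRUE` is available.

## Pairwise comparison

Profile similarity is the Pearson correlation of the paired linear
proportions (covariance over the product of standard deviations). For
directional analysis, per-miRNA ratios `log2((a + eps)/(b + eps))` are
sorted ascending into the crescent curve; miRNAs are classified up
(ratio > 0) or down (< 0), and the split is tested against equal
proportions with a 1-df chi-square goodness-of-fit test, no continuity
correction, exact zeros excluded. The median is computed over all
ratios, zeros included, and marks the curve's centre. Fold changes are
also binned on the linear scale (< 0.5×, 0.5–2×, > 2×), and "changed by
more than 1 fold" is implemented as |log2 ratio| > 1.

**Pseudocount.** Zero proportions would make log ratios infinite. The
default `eps` is half a read in the proportion units of the shallower
library, `0.5 / min(total miRNA reads)`: every ratio stays finite, the
shrinkage vanishes as depth grows, and the same policy is reused for the
additivity deviations so the two stages are comparable. `eps = 0` is
accepted when no zeros occur.

## Additivity

The expected hybrid profile is the dosage-weighted mid-parent value:

$$E[\mathrm{hybrid}]_m = \frac{\sum_g d_g \, p_{g,m}}{\sum_g d_g},$$

with $d_g$ the dosage of parental genome $g$ and $p_{g,m}$ the parental
proportion of miRNA $m$ — i.e. $(PP+AA)/2$ for PA and $(PP+2AA)/3$ for
PAA. Parental profiles enter as proportions (the expression unit of the
workflow); a weighted mean of proportion vectors is itself a proportion
vector, so no renormalization is applied. Deviations
`log2((obs + eps)/(exp + eps))` are summarized by the over/under split
(chi-square as above), the median, and the fraction of miRNAs strictly
inside the band `-band < deviation < band` (default `band = 1`, i.e.
within two-fold of expectation). Band boundaries count as outside —
the band is a strict inequality. Deviations within `1e-12` of zero count
as exactly additive: this is a floating-point guard, needed because a
profile that equals its expectation up to machine rounding would
otherwise be classified systematically to one side, not a biological
threshold.

## The synthetic-data generator

The generator exists so that every stage has a ground truth to be tested
against. It emulates the statistical structure the analysis assumes,
with these default study conditions:

* **Four libraries** (PP, AA, PA, PAA) over a 204-miRNA reference —
  the size of a conserved miRNA set shared by all libraries — at 2e5
  reads each, 15 contaminant features, contaminant read fraction 0.15
  (miRNAs dominate a good small-RNA library).
* **True parental proportions** drawn log-normal (meanlog 0, sdlog 1)
  and normalized: a several-orders-of-magnitude dynamic range typical of
  miRNA expression. The within-library count distribution of real
  libraries is not recoverable from a published summary; the log-normal
  is a stand-in, not an inference.
* **Hybrid truths** are the dosage-weighted parental mixtures, times
  `2^effect` for a planted non-additive subset, renormalized. Effects
  are multiplicative in proportion space because departures from
  additivity are naturally fold-type; by default 30% of triploid miRNAs
  carry a +1 log2 effect (the PA hybrid is fully additive), so the
  triploid's planted over-expressed share is a known 30% against which
  recovery can be measured.
* **Reads.** miRNA reads are exact copies of their mature feature
  sequence, 3'-truncated by 1–3 nt with probabilities 0.05/0.02/0.01
  (imprecise processing and degradation). Contaminant reads come mostly
  from a pool of recurrent fragments of the rRNA/tRNA/repeat/exon/intron
  features — degradation products recur at preferred sites, and the pool
  is derived deterministically from the reference so all libraries share
  it — plus a small rate (0.0065) of uniform random substrings forming
  each library's private tail. These two rates set the pairwise shared
  fraction of unique sequences, which lands at roughly 92–95% under the
  default depth, the regime the analysis is designed for.
* **Lengths.** Mature-miRNA features are 20–23 nt with more than half at
  22 nt, and the contaminant length model over 14–30 nt also peaks at
  22, so the read-length histogram of a default library has its mode at
  22 nt. The 22-nt mass must dominate at the *feature* level because the
  realized histogram weights lengths by expression: with few miRNAs, a
  highly expressed 21-nt miRNA can otherwise shift the mode.
* **Seeding.** One global integer seed is split deterministically per
  stage and library; identical seeds give byte-identical libraries,
  references and pipeline outputs.

What the generator does **not** model: sequencing errors, adapter
chemistry, strand-specific biases, isomiR families beyond simple 3'
truncation, or any phylogenetic structure between the parental genomes.
Passing tests therefore demonstrate that the statistical machinery is
correct on data satisfying the model's assumptions, not that a real
library meets them.

## Calibration and power, at desk scale

Two simulation studies accompany the package (in the test suite and
`scripts/acceptance.R`); their problem sizes are chosen so each runs in
well under a minute at count level:

* **Type-I calibration** — 1000 fully additive four-library replicates
  (50 miRNAs, 1e5 reads): the PAA-vs-PA up/down chi-square at
  $\alpha = 0.05$ rejects in about 3–7% of replicates. The rate sits
  slightly below nominal because the up/down counts come from proportion
  vectors that each sum to 1, which induces a weak negative dependence
  between miRNAs, and because a two-category chi-square on ~50 trials is
  discrete.
* **Recovery** — planting the +1 log2 effect in 30% of 204 triploid
  miRNAs at 1e5 reads: the estimated over-expressed share lands within
  5 percentage points of the planted 30% and the over/under imbalance is
  called at p < 0.01 in essentially every one of 200 replicates.

## Numerical and design choices, collected

* Chi-square always 1 df, no continuity correction, zeros excluded
  (except that an input with *no* non-zero deviations returns
  statistic 0, p 1: perfect additivity is evidence of balance, not a
  degenerate test).
* Whether a published 70/30-style split excluded exact zeros, and
  whether a continuity correction was used, is generally not stated in
  summary-level reports; the package's conventions above are recorded in
  every output object.
* Multi-locus tags pool categories across all hits before priority
  resolution; how disagreeing loci should be counted is a genuine open
  choice, and pooling-then-priority keeps the one-annotation invariant.
* The additivity universe defaults to the cross-library detected
  intersection and is recorded in the run report; restricting or
  widening it is a caller decision.
* TSV is the only tabular output format, proportions at 6 significant
  digits in the expression matrix; everything a run writes is
  reproducible byte-for-byte from the manifest and seed.

## Limitations

The workflow quantifies *global* directional shifts; it does not test
individual miRNAs for differential expression and applies no
multiple-testing machinery, because a two-library design without
replicates cannot support per-feature inference. Exact matching ignores
sequencing errors (reads with errors simply stay unmapped, slightly
deflating the mapped fraction). The mid-parent expectation inherits any
bias in the parental profiles; with proportions as the expression unit,
a global amplitude change that preserves composition is invisible by
construction — only compositional shifts are detectable.
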