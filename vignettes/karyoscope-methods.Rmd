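---
title: "Methods: coverage-based sex-chromosome calling, genome landscapes and macrosynteny painting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based sex-chromosome calling, genome landscapes and macrosynteny painting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoscope)
library(dplyr)
```

karyoscope implements three karyotype-level analyses that become possible
once a genome assembly reaches chromosome scale, together with a seeded
synthetic-data generator that makes every stage testable without any
sequencing data. This vignette is the package's account of the underlying
models, the tunable parameters, the numerical conventions, and what the
synthetic tests do and do not demonstrate about real data.

## The coverage model behind sex-chromosome calling

In an XX/XO system, females carry two copies of the X chromosome and males
one, while both sexes carry two copies of every autosome. If a female and a
male library are sequenced and mapped to the same assembly, the expected
per-base depth of an X-linked scaffold in the male is half its female
expectation, while autosomes match. After scaling each library to a common
unit, the per-window statistic

$$ r_w = \log_2\!\frac{\hat d_{F,w}}{\hat d_{M,w}} $$

concentrates near 1 on X-linked scaffolds and near 0 on autosomes.
`scan_sex_chromosomes()` computes windowed depth for both samples (100-kb
windows by default), normalizes, forms the ratio track, and calls each
scaffold from the median of its unmasked window ratios.

Key choices:

* **Normalization is per-sample median-window scaling.** Each track is
  divided by its own median window depth. The median is used deliberately:
  X-linked windows are a minority of the genome, so the median is set by
  autosomal windows and is robust to the very signal being detected. Total-
  count scaling would be biased by the X fraction itself. The output is
  invariant to multiplying either library by any positive constant, and the
  test suite asserts this invariance at the call level.
* **Pro-rata base attribution.** A read overlapping a window boundary
  contributes to each window proportionally to its overlap, so the sum of
  attributed bases over windows equals the number of aligned bases exactly.
  This conservation is asserted exactly in the tests, which whole-read
  assignment by start position would not satisfy.
* **Call bands.** There is no universally agreed numeric threshold for "the
  characteristic twofold difference"; the defaults here are a log2 band of
  $[0.6, 1.4]$ for X-linked and $[-0.4, 0.4]$ for autosomal, with anything
  else — or any scaffold with fewer than half its windows unmasked —
  reported as ambiguous rather than forced into a class. Both bands are
  exposed as arguments. At 10× or more simulated depth the per-window noise
  is far smaller than the band half-width, which is why parameter recovery
  is essentially deterministic in the tests.
* **Masking.** Windows with zero raw depth in either sample carry no ratio
  (log2 is undefined there); `min_depth` raises that threshold if desired.
  Degenerate windows are masked, never fatal. Median over an even number of
  windows uses the usual midpoint convention.
* **MAPQ.** `min_mapq` defaults to 0 because simulated placements carry no
  meaningful mapping quality; with real alignments a positive threshold
  filters multi-mappers upstream of the ratio.

## Windowed landscape statistics

`gc_sliding()` reports GC content in 100-kb windows advancing by 1 kb.
Windows are anchored at 0-based multiples of the step; trailing windows are
truncated and *retained*, flagged with their valid-base count, rather than
silently dropped — no data loss, and the caller can filter on `n_valid`.
GC is computed over unambiguous bases only (N and other ambiguity codes are
excluded from the denominator); soft-masked lowercase bases count as their
base identity, because repeat status comes from the repeat annotation, not
from the case of the sequence. On full windows the statistic is exactly
strand-symmetric, which the suite verifies against the reverse complement.

`feature_density()` counts each gene or repeat in exactly one window — the
window containing its anchor. The anchor is the feature start by default
(midpoint on request); whether published per-window counts use starts or
any-overlap is rarely stated, so the package picks one rule, documents it,
and guarantees conservation: track totals always equal input feature
counts.

`n50()` returns the largest length $L$ in the input such that scaffolds of
length $\ge L$ cover at least half the assembly; the test suite checks it
against a brute-force implementation on every multiset of up to six lengths
drawn from 1..10 (N50 is permutation-invariant, so multisets exhaust the
ordered-list case space at a fraction of the cost).
`completeness_percent()` is the benchmark-orthologs arithmetic
$100 \cdot \text{found}/\text{total}$, reported at full precision and
rounded to the integer percent such figures are usually printed at.

### Tandem gene clusters

Expanded gene families in parasite genomes often sit in tandem arrays.
`find_clusters()` sweeps each scaffold's genes in start order and joins a
gene to the open cluster when the gap between its start and the rightmost
gene end *seen so far* is at most `max_gap` (overlap counts as gap 0).
Measuring from the rightmost end seen — rather than only the previous
gene's end — is what makes the single sweep exactly equivalent to
transitive closure under the pairwise gap relation, including the corner
case of a long gene that fully contains later short ones; the equivalence
is property-tested against a naive pairwise-closure oracle. Defaults
`max_gap = 10` kb and `min_size = 3` are the package's own: visual "darker
bands" in published gene-location plots correspond to no published numbers,
so the thresholds are explicit, documented and exposed.

## Macrosynteny painting and fusion signatures

Given one-to-one orthologs between the focal genome and a reference
karyotype, `paint()` tiles the focal scaffolds into 500-kb windows and
reports, per window, the fraction of its orthologs attributed to each
reference chromosome. The denominator is the orthologs in the window (not
all genes), fractions per informative window sum to 1 (asserted to 1e-9),
and windows with zero orthologs are flagged `no_synteny` instead of being
given fractions. Window totals are reported so users can filter sparse
windows themselves.

`summarize_homology()` assigns each window a dominant reference chromosome
(argmax fraction, provided it reaches `min_window_fraction = 0.5`; ties are
broken deterministically by the declared label order) and accumulates
dominant-window widths into per-scaffold spans. A scaffold whose spans
attribute at least `min_span_bp = 1` Mb to two or more reference
chromosomes carries a fusion signature — the painting pattern left by an
ancestral chromosome fusion or translocation. Both thresholds are
documented defaults, not biology: published statements like "primarily
homologous" are qualitative, so the package makes its operational
definition explicit. `detect_breakpoints()` reads the dominant labels along
each scaffold and reports every change point between informative windows,
skipping `no_synteny` windows so a sparse window cannot split a span;
breakpoint resolution is therefore one painting window. Reciprocal painting
(reference windows painted by focal scaffolds) needs no separate code path:
swap the focal and reference columns and re-run.

## The synthetic-data generator

The generator exists so that every analysis has a ground truth to recover.
Its defaults are the package's fixed study conditions:

* **Karyotype.** Five scaffolds: one 3.5-Mb X plus autosomes of 2, 1.5, 1
  and 0.5 Mb. The X is the largest scaffold, mirroring the situation where
  the largest assembly scaffold turns out to be X. The X is simulated with
  a GC-rich centre and repeat-rich arms (per-100-kb Poisson repeat rates 20
  on arms vs 5 in the centre), the arm/centre organisation characteristic
  of nematode chromosomes; global GC sits near 45%.
* **Why a 3.5-Mb X.** The planted ancestry of the X is 4:3 —
  its first 2 Mb descend from reference chromosome II and the remaining
  1.5 Mb from chromosome IV, a 1/5-scale rendering of a real 10 Mb : 7.5 Mb
  fusion configuration. Both segments must exceed the 1-Mb `min_span_bp`
  default for the fusion signature to be detectable at the 500-kb painting
  window, which fixes the X at 3.5 Mb rather than capping all scaffolds at
  2 Mb; the whole genome is 8.5 Mb and the full pipeline runs in seconds.
* **Sequences** are drawn base-by-base with a per-position GC probability
  (arms vs centre), so windowed GC has a known expectation and binomial
  error — the oracle used in the tests.
* **Reads** are single-end fixed-length placements (100 bp) drawn uniformly
  per scaffold with Poisson counts of expectation
  $\text{copy} \times \text{depth} \times L / (2 \times \text{readlen})$,
  copy 2 everywhere except the male X (copy 1; males are taken to be XO —
  no Y is simulated, consistent with the halved-coverage logic). Under this
  convention `mean_depth` *is* the realized per-base depth of any two-copy
  region, so "simulated at 20×" means what a sequencing centre would mean.
  No sequencing-error model, quality strings or pairing: coverage analysis
  consumes only positions. Default depth is 20×.
* **Genes** are placed uniformly at 366 per Mb (the density of ~31k genes
  in an 84.5-Mb genome), with two planted tandem clusters (5 genes, gaps
  ≤ 2 kb) whose recovery the cluster tests assert.
* **Orthologs** are sampled at 20 pairs/Mb with 50% dropout by default —
  deliberately sparse and lossy, so painting must work at realistic
  one-to-one ortholog densities. Positions falling outside any fusion-map
  interval are labelled `"none"`, emulating no-synteny regions.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: mappability and GC bias in read depth, paired-end
artefacts, collapsed repeats and assembly errors (which produce apparent
depth anomalies unrelated to sex linkage), heterozygosity, partial X
degeneration or Y remnants, and non-uniform gene placement. The recovery
results on synthetic data demonstrate correctness of the statistics, not
robustness to those confounders; with real libraries the masking threshold,
MAPQ filter and call bands are the knobs that absorb them.

## Numerical and format conventions

* All internal intervals are 0-based half-open; GFF3 and SAM are emitted
  1-based per their standards, BED/BEDGRAPH 0-based half-open. Window
  arithmetic is therefore `floor(position / window_size)` with no edge
  ambiguity, and the last window of a scaffold may be short.
* Determinism: every simulator takes an explicit seed and restores the
  caller's RNG state; identical configuration and seed give byte-identical
  files. The pipeline derives stage seeds from the run seed by fixed small
  offsets, and stamps every table header with the package version, seed and
  a hash of the analysis configuration (the output directory is excluded
  from the hash so relocating a run does not change its identity).
* Pipeline stage files are written to a `.partial` name and renamed on
  completion, so an aborted run cannot leave a truncated file that looks
  complete.
* Problem sizes in the test suite (a 8.5-Mb genome at 10–20×, 200-kb GC
  oracle sequences, 20-seed recovery loops) were chosen as the smallest
  scales at which the sampling errors of every asserted statistic are an
  order of magnitude below the asserted tolerances; the whole suite runs in
  a few minutes on one core.

## Known limitations

* Calls are per-scaffold medians; a scaffold that is a chimera of X-linked
  and autosomal material is reported as ambiguous (or by its majority), not
  segmented — copy-number segmentation is out of scope.
* No GC-bias correction of depth is applied before the ratio.
* Painting uses ortholog membership only; gene order within windows
  (collinearity/microsynteny) is ignored, so intra-chromosomal
  rearrangements are invisible.
* Fusion detection needs both ancestral segments to exceed `min_span_bp`;
  small translocated fragments fall below the default and must be sought by
  lowering the threshold or inspecting the painting matrix directly.
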