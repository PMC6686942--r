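# karyoscope

Karyotype-level analysis of chromosome-scale genome assemblies, built for
the questions that open up once a fragmented draft becomes a handful of
chromosome-sized scaffolds:

* **Which scaffold is the X?** In XX/XO species (many nematodes among
  them), an X-linked scaffold shows a twofold female:male sequencing-depth
  contrast. `scan_sex_chromosomes()` computes windowed depth for a female
  and a male library, median-normalizes each, forms the per-window
  statistic `log2(d_F / d_M)` — near 1 on X, near 0 on autosomes — and
  calls every scaffold X-linked, autosomal or ambiguous from its median
  window ratio.
* **What does the genome landscape look like?** Sliding-window GC
  (100 kb / 1 kb), gene and repeat density per 100 kb, assembly summaries
  (N50, total length, global GC), completeness arithmetic, and tandem
  gene-cluster detection by a gap sweep.
* **How does the karyotype map onto a reference?** Macrosynteny
  "chromosome painting": per 500-kb window, the fraction of one-to-one
  orthologs attributed to each reference chromosome, per-scaffold dominant
  homology, no-synteny flags, and detection of fusion signatures —
  scaffolds whose painted spans attribute ≥ 1 Mb to two or more reference
  chromosomes, with breakpoint localisation to window resolution.

A seeded synthetic-data generator (`simulate_genome()`,
`simulate_reads()`, `simulate_orthologs()`, `write_fixture_bundle()`)
produces toy genomes with a planted X, arm/centre GC and repeat structure,
planted tandem clusters and a planted chrII+chrIV fusion, so the entire
pipeline is testable end to end with no external data.

Everything is tidyverse-native: functions take data frames and return
tibbles, result objects support `tidy()`, `glance()` and `autoplot()`, and
standard formats (FASTA, GFF3, BED, SAM/BAM, BEDGRAPH, TSV) are read
through Biostrings / Rsamtools / rtracklayer.

## Worked example

```r
library(karyoscope)

genome  <- simulate_genome(seed = 1)                       # 5 scaffolds, one planted X
reads_f <- simulate_reads(genome, "female", mean_depth = 20, seed = 2)
reads_m <- simulate_reads(genome, "male",   mean_depth = 20, seed = 3)

scan <- scan_sex_chromosomes(reads_f, reads_m, genome)
tidy(scan)
#> # A tibble: 5 × 6
#>   scaffold  length n_windows n_unmasked median_log2_ratio call
#>   <chr>      <dbl>     <int>      <int>             <dbl> <chr>
#> 1 scf_X    3500000        35         35           0.989   X-linked
#> 2 scf_1    2000000        20         20          -0.0102  autosomal
#> 3 scf_2    1500000        15         15          -0.0182  autosomal
#> 4 scf_3    1000000        10         10          -0.00933 autosomal
#> 5 scf_4     500000         5          5          -0.0248  autosomal
```

The planted X sits at a median log2 female:male ratio of 0.989 — the
twofold coverage contrast of a single-copy male X — while every autosome
sits within a few percent of 0.

```r
orth <- simulate_orthologs(genome, n_per_mb = 20, dropout = 0.5, seed = 4)
hom  <- summarize_homology(paint(orth, make_windows(genome, 5e5)))
hom
#> # A tibble: 5 × 4
#>   scaffold dominant_ref n_ref_over_threshold fusion_flag
#>   <chr>    <chr>                       <int> <lgl>
#> 1 scf_X    II                              2 TRUE
#> 2 scf_1    I                               1 FALSE
#> 3 scf_2    III                             1 FALSE
#> 4 scf_3    V                               1 FALSE
#> 5 scf_4    X                               0 FALSE
#> # fusion signature on: scf_X

detect_breakpoints(hom)
#> # A tibble: 1 × 4
#>   scaffold position from  to
#>   <chr>       <dbl> <chr> <chr>
#> 1 scf_X     2000000 II    IV
```

Painting recovers the planted ancestry of the X — 2 Mb descending from
reference chromosome II and 1.5 Mb from chromosome IV — flags it as the
only fusion-signature scaffold, and places the II→IV breakpoint at
2,000,000 bp, exactly the planted boundary.

```r
assembly_stats(genome)
#> # A tibble: 1 × 5
#>   n_scaffolds total_length     n50 largest global_gc
#> 1           5      8500000 2000000 3500000     0.451

completeness_percent(854, 982)
#> # A tibble: 1 × 4
#>   found total percent percent_rounded
#> 1   854   982    87.0              87
```

The whole analysis also runs as one seeded, logged command —
`run_pipeline(list(out_dir = "out", seed = 1))` or, from a shell,
`exec/karyoscope run --seed 1 --out out` — writing every stage table
(ratio windows, sex calls, GC/density tracks, clusters, painting matrix,
homology report) plus a combined per-scaffold report, each stamped with
the package version, seed and configuration hash.

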