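# Shared fixtures and independent oracles. Oracles are deliberately naive
# (loops, pairwise closure, substring counting) and never call the code paths
# they check.

suppressPackageStartupMessages(library(dplyr))

one_scaffold_genome <- function(length = 1e6, is_x = FALSE, seed = 1, ...) {
  specs <- scaffold_spec("s1", length, is_x = is_x)
  simulate_genome(specs, seed = seed, genes_per_mb = 0,
                  cluster_families = 0, sequences = FALSE, ...)
}

toy_genome <- function(seed = 1, sequences = FALSE, ...) {
  simulate_genome(default_scaffold_specs(), seed = seed,
                  sequences = sequences, ...)
}

# N50 by direct definition: largest length L among the input lengths such
# that scaffolds of length >= L cover at least half the total.
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  stop("unreachable")
}

# GC per window by substring counting
oracle_gc_windows <- function(seq_chr, window_size, step) {
  len <- nchar(seq_chr)
  starts <- seq(0, len - 1, by = step)
  vapply(starts, function(s) {
    win <- toupper(substr(seq_chr, s + 1, min(s + window_size, len)))
    chars <- strsplit(win, "")[[1]]
    gc <- sum(chars %in% c("G", "C"))
    valid <- sum(chars %in% c("A", "C", "G", "T"))
    if (valid == 0) NA_real_ else gc / valid
  }, numeric(1))
}

# transitive closure under the pairwise gap relation: merge any two genes
# whose interval gap (0 for overlap) is <= max_gap, repeatedly
oracle_cluster_partition <- function(genes, max_gap) {
  n <- nrow(genes)
  comp <- seq_len(n)
  gap <- function(i, j) {
    if (genes$scaffold[i] != genes$scaffold[j]) return(Inf)
    max(0, max(genes$start[i], genes$start[j]) -
          min(genes$end[i], genes$end[j]))
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (comp[i] != comp[j] && gap(i, j) <= max_gap) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  split(genes$gene_id, comp)
}

# per-window ortholog tallies by explicit looping
oracle_paint_tally <- function(orthologs, grid) {
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    w <- grid[i, ]
    hit <- orthologs$focal_scaffold == w$scaffold &
      orthologs$focal_start >= w$start & orthologs$focal_start < w$end
    if (!any(hit)) {
      return(tibble::tibble(scaffold = w$scaffold, start = w$start,
                            ref_chromosome = character(0)[0],
                            count = integer(0)))
    }
    as.data.frame(table(orthologs$ref_chromosome[hit]),
                  stringsAsFactors = FALSE) |>
      setNames(c("ref_chromosome", "count")) |>
      mutate(scaffold = w$scaffold, start = w$start, .before = 1)
  })
}

revcomp_chr <- function(seq_chr) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_chr)))
}

random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}

random_genes <- function(n, scaffold_len, seed, gene_len_max = 5000) {
  withr::with_seed(seed, {
    start <- floor(runif(n, 0, scaffold_len - gene_len_max))
    len <- floor(runif(n, 1, gene_len_max))
    tibble::tibble(scaffold = "s1", start = start, end = start + len,
                   gene_id = sprintf("g%03d", seq_len(n)))
  })
}
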