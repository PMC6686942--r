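#' Describe one scaffold of a synthetic genome
#'
#' A scaffold specification gives the length, X status and the arm/centre
#' composition structure of one simulated scaffold. Nematode chromosomes
#' typically carry repeat-rich, GC-poor arms flanking a gene-dense centre;
#' `arm_fraction` is the portion of each scaffold end treated as "arm", and
#' the GC and repeat parameters apply per region.
#'
#' @param name Scaffold identifier.
#' @param length Scaffold length in bp (> 0).
#' @param is_x Logical; simulate this scaffold at single copy in males (XO).
#' @param gc_center,gc_arms Per-base probability of a G/C base in the centre /
#'   arm regions, in `[0, 1]`.
#' @param arm_fraction Fraction of each scaffold end treated as arm, in
#'   `[0, 0.5]`.
#' @param repeat_rate_center,repeat_rate_arms Expected repeat intervals per
#'   100 kb in each region (Poisson rates, >= 0).
#' @return A one-row tibble; rows from several calls bind into a scaffold
#'   specification table.
#' @examples
#' scaffold_spec("chrX", 2e6, is_x = TRUE, gc_center = 0.48, gc_arms = 0.42)
#' @export
scaffold_spec <- function(name, length, is_x = FALSE,
                          gc_center = 0.45, gc_arms = 0.45,
                          arm_fraction = 0.25,
                          repeat_rate_center = 10, repeat_rate_arms = 10) {
  spec <- tibble(
    name = as.character(name), length = as.numeric(length),
    is_x = isTRUE(is_x),
    gc_center = gc_center, gc_arms = gc_arms, arm_fraction = arm_fraction,
    repeat_rate_center = repeat_rate_center,
    repeat_rate_arms = repeat_rate_arms
  )
  validate_scaffold_specs(spec)
  spec
}

validate_scaffold_specs <- function(specs) {
  stopifnot(is.data.frame(specs), nrow(specs) > 0)
  needed <- c("name", "length", "is_x", "gc_center", "gc_arms",
              "arm_fraction", "repeat_rate_center", "repeat_rate_arms")
  missing_cols <- setdiff(needed, names(specs))
  if (length(missing_cols) > 0) {
    abort(paste0("scaffold spec is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- specs$length <= 0
  if (any(bad)) {
    abort(paste0("non-positive length for scaffold(s): ",
                 paste(specs$name[bad], collapse = ", ")))
  }
  bad <- specs$repeat_rate_center < 0 | specs$repeat_rate_arms < 0
  if (any(bad)) {
    abort(paste0("negative repeat rate for scaffold(s): ",
                 paste(specs$name[bad], collapse = ", ")))
  }
  bad <- specs$gc_center < 0 | specs$gc_center > 1 |
    specs$gc_arms < 0 | specs$gc_arms > 1
  if (any(bad)) {
    abort(paste0("GC probabilities outside [0, 1] for scaffold(s): ",
                 paste(specs$name[bad], collapse = ", ")))
  }
  bad <- specs$arm_fraction < 0 | specs$arm_fraction > 0.5
  if (any(bad)) {
    abort(paste0("arm_fraction outside [0, 0.5] for scaffold(s): ",
                 paste(specs$name[bad], collapse = ", ")))
  }
  if (anyDuplicated(specs$name)) abort("duplicated scaffold names")
  invisible(specs)
}

#' Default five-scaffold toy karyotype
#'
#' One 3.5-Mb X scaffold with a GC-rich centre and repeat-rich arms, plus four
#' autosomes of 2, 1.5, 1 and 0.5 Mb, at a global GC near 0.45. The X carries
#' the planted two-chromosome ancestry used by [default_fusion_map()]: its
#' first 2 Mb descend from reference chromosome II and the remaining 1.5 Mb
#' from chromosome IV (a 10:7.5 span ratio), so macrosynteny painting has a
#' genuine fusion signature to recover while the whole pipeline still runs in
#' seconds.
#'
#' @return A scaffold specification tibble (see [scaffold_spec()]).
#' @export
default_scaffold_specs <- function() {
  bind_rows(
    scaffold_spec("scf_X", 3.5e6, is_x = TRUE, gc_center = 0.48,
                  gc_arms = 0.42, arm_fraction = 0.25,
                  repeat_rate_center = 5, repeat_rate_arms = 20),
    scaffold_spec("scf_1", 2.0e6, gc_center = 0.45, gc_arms = 0.45,
                  repeat_rate_center = 10, repeat_rate_arms = 10),
    scaffold_spec("scf_2", 1.5e6, gc_center = 0.44, gc_arms = 0.47,
                  repeat_rate_center = 8, repeat_rate_arms = 14),
    scaffold_spec("scf_3", 1.0e6, gc_center = 0.46, gc_arms = 0.44,
                  repeat_rate_center = 12, repeat_rate_arms = 8),
    scaffold_spec("scf_4", 0.5e6, gc_center = 0.45, gc_arms = 0.45,
                  repeat_rate_center = 10, repeat_rate_arms = 10)
  )
}

#' Default fusion map for a simulated genome
#'
#' Assigns every scaffold a reference-chromosome ancestry. The X scaffold is
#' split 4:3 along its length between reference chromosomes II and IV — the
#' planted fusion the painting stage must recover — and each autosome maps
#' wholly to a single reference chromosome (cycling I, III, V, X).
#'
#' @param specs Scaffold specification tibble.
#' @return A tibble with columns `focal_scaffold`, `start`, `end`,
#'   `ref_chromosome` (0-based half-open intervals).
#' @export
default_fusion_map <- function(specs = default_scaffold_specs()) {
  validate_scaffold_specs(specs)
  auto_refs <- c("I", "III", "V", "X")
  rows <- list()
  auto_i <- 0L
  for (i in seq_len(nrow(specs))) {
    sc <- specs[i, ]
    if (sc$is_x) {
      brk <- round(sc$length * 4 / 7)
      rows[[length(rows) + 1L]] <- tibble(
        focal_scaffold = sc$name, start = c(0, brk), end = c(brk, sc$length),
        ref_chromosome = c("II", "IV")
      )
    } else {
      auto_i <- auto_i + 1L
      rows[[length(rows) + 1L]] <- tibble(
        focal_scaffold = sc$name, start = 0, end = sc$length,
        ref_chromosome = auto_refs[((auto_i - 1L) %% length(auto_refs)) + 1L]
      )
    }
  }
  bind_rows(rows)
}

#' Simulate a toy genome with structured GC, repeats and genes
#'
#' Draws each scaffold's sequence base-by-base with per-position GC
#' probability `gc_arms` within the first and last `arm_fraction` of the
#' scaffold and `gc_center` elsewhere; places repeat intervals as a Poisson
#' process with the region-specific per-100-kb rate; places genes uniformly at
#' `genes_per_mb`, plus a configurable number of planted tandem gene clusters
#' (same `family` label, small inter-gene gaps) that the cluster detector
#' should recover. Identical `(specs, seed)` give identical output.
#'
#' @param specs Scaffold specification tibble ([scaffold_spec()] rows).
#' @param seed Integer seed; all randomness is derived from it.
#' @param genes_per_mb Expected genes per Mb (uniform placement).
#' @param gene_length_range Min/max gene length in bp.
#' @param repeat_length Repeat interval length in bp.
#' @param cluster_families Number of planted tandem gene clusters.
#' @param cluster_size Genes per planted cluster.
#' @param cluster_gap Maximum inter-gene gap within a planted cluster, bp.
#' @param n_run_rate Expected N-runs per Mb (runs of `n_run_length` Ns).
#' @param n_run_length Length of each N run, bp.
#' @param sequences If `FALSE`, skip sequence generation (annotations and read
#'   placement only need lengths; large parameter sweeps use this).
#' @param fusion_map Fusion map tibble; defaults to [default_fusion_map()] of
#'   `specs`.
#' @return A `genome_model` list: `scaffolds` (spec tibble), `sequences`
#'   (named [Biostrings::DNAStringSet] or `NULL`), `genes`, `repeats`,
#'   `fusion_map` tibbles, `truth_x` (character), `cluster_truth`, `seed`.
#'   All interval columns are 0-based half-open.
#' @examples
#' g <- simulate_genome(default_scaffold_specs(), seed = 1)
#' g$truth_x
#' @export
simulate_genome <- function(specs = default_scaffold_specs(), seed = 1,
                            genes_per_mb = 366,
                            gene_length_range = c(500, 3000),
                            repeat_length = 200,
                            cluster_families = 2, cluster_size = 5,
                            cluster_gap = 2000,
                            n_run_rate = 0, n_run_length = 200,
                            sequences = TRUE,
                            fusion_map = NULL) {
  validate_scaffold_specs(specs)
  specs <- as_tibble(specs)
  if (is.null(fusion_map)) fusion_map <- default_fusion_map(specs)
  withr::local_seed(as.integer(seed))

  seqs <- if (sequences) {
    s <- vapply(seq_len(nrow(specs)), function(i) {
      simulate_scaffold_sequence(specs[i, ], n_run_rate, n_run_length)
    }, character(1))
    Biostrings::DNAStringSet(setNames(s, specs$name))
  } else NULL

  repeats <- purrr::map_dfr(seq_len(nrow(specs)), function(i) {
    simulate_repeats_one(specs[i, ], repeat_length)
  })

  genes <- simulate_genes(specs, genes_per_mb, gene_length_range,
                          cluster_families, cluster_size, cluster_gap)

  structure(list(
    scaffolds = specs,
    sequences = seqs,
    genes = genes$genes,
    repeats = repeats,
    fusion_map = as_tibble(fusion_map),
    truth_x = specs$name[specs$is_x],
    cluster_truth = genes$cluster_truth,
    seed = as.integer(seed)
  ), class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", nrow(x$scaffolds), " scaffolds, ",
      format(sum(x$scaffolds$length), big.mark = ","), " bp; X: ",
      if (length(x$truth_x)) paste(x$truth_x, collapse = ", ") else "none",
      "; ", nrow(x$genes), " genes, ", nrow(x$repeats), " repeats",
      if (is.null(x$sequences)) " (no sequences)" else "", "\n", sep = "")
  invisible(x)
}

# Region model: positions [0, arm) and [len - arm, len) are "arms".
arm_mask <- function(length, arm_fraction) {
  arm <- floor(length * arm_fraction)
  pos <- seq_len(length) - 1L
  pos < arm | pos >= (length - arm)
}

simulate_scaffold_sequence <- function(spec, n_run_rate, n_run_length) {
  len <- as.integer(spec$length)
  in_arm <- arm_mask(len, spec$arm_fraction)
  p_gc <- ifelse(in_arm, spec$gc_arms, spec$gc_center)
  is_gc <- rbinom(len, 1L, p_gc) == 1L
  # within GC pick G/C equally; within AT pick A/T equally
  pick <- rbinom(len, 1L, 0.5) == 1L
  base <- character(len)
  base[is_gc & pick] <- "G"
  base[is_gc & !pick] <- "C"
  base[!is_gc & pick] <- "A"
  base[!is_gc & !pick] <- "T"
  if (n_run_rate > 0) {
    n_runs <- rpois(1L, n_run_rate * len / 1e6)
    if (n_runs > 0) {
      starts <- floor(runif(n_runs, 0, max(1, len - n_run_length)))
      for (s in starts) base[(s + 1):min(len, s + n_run_length)] <- "N"
    }
  }
  paste(base, collapse = "")
}

simulate_repeats_one <- function(spec, repeat_length) {
  len <- spec$length
  arm <- floor(len * spec$arm_fraction)
  regions <- tibble(
    start = c(0, arm, len - arm),
    end = c(arm, len - arm, len),
    rate = c(spec$repeat_rate_arms, spec$repeat_rate_center,
             spec$repeat_rate_arms)
  ) |> filter(.data$end > .data$start)
  out <- purrr::map_dfr(seq_len(nrow(regions)), function(j) {
    r <- regions[j, ]
    n <- rpois(1L, r$rate * (r$end - r$start) / 1e5)
    if (n == 0) return(tibble(start = numeric(0), end = numeric(0)))
    s <- floor(runif(n, r$start, r$end))
    tibble(start = s, end = pmin(s + repeat_length, len))
  })
  if (nrow(out) == 0) {
    return(tibble(scaffold = character(0), start = numeric(0),
                  end = numeric(0)))
  }
  tibble(scaffold = spec$name, start = out$start, end = out$end) |>
    arrange(.data$start)
}

simulate_genes <- function(specs, genes_per_mb, gene_length_range,
                           cluster_families, cluster_size, cluster_gap) {
  genes <- purrr::map_dfr(seq_len(nrow(specs)), function(i) {
    sc <- specs[i, ]
    n <- rpois(1L, genes_per_mb * sc$length / 1e6)
    if (n == 0) return(NULL)
    glen <- floor(runif(n, gene_length_range[1], gene_length_range[2] + 1))
    start <- floor(runif(n, 0, pmax(1, sc$length - glen)))
    tibble(scaffold = sc$name, start = start, end = start + glen,
           strand = sample(c("+", "-"), n, replace = TRUE),
           family = "none")
  })
  if (nrow(genes) == 0) {
    genes <- tibble(scaffold = character(0), start = numeric(0),
                    end = numeric(0), strand = character(0),
                    family = character(0))
  }
  cluster_truth <- tibble(family = character(0), scaffold = character(0),
                          start = numeric(0), end = numeric(0),
                          n_genes = integer(0))
  if (cluster_families > 0) {
    fam_rows <- list()
    for (k in seq_len(cluster_families)) {
      sc <- specs[sample.int(nrow(specs), 1L), ]
      fam <- paste0("fam", LETTERS[k])
      glen <- floor(runif(cluster_size, gene_length_range[1],
                          gene_length_range[2] + 1))
      gaps <- floor(runif(cluster_size, 0, cluster_gap + 1))
      span <- sum(glen) + sum(gaps[-1])
      anchor <- floor(runif(1, 0, max(1, sc$length - span)))
      starts <- anchor + head(cumsum(c(0, glen[-cluster_size] +
                                         gaps[-1])), cluster_size)
      fam_rows[[k]] <- tibble(scaffold = sc$name, start = starts,
                              end = starts + glen,
                              strand = sample(c("+", "-"), cluster_size,
                                              replace = TRUE),
                              family = fam)
      cluster_truth <- bind_rows(cluster_truth, tibble(
        family = fam, scaffold = sc$name, start = starts[1],
        end = starts[cluster_size] + glen[cluster_size],
        n_genes = as.integer(cluster_size)))
    }
    genes <- bind_rows(genes, bind_rows(fam_rows))
  }
  genes <- genes |>
    arrange(.data$scaffold, .data$start) |>
    mutate(gene_id = sprintf("g%05d", row_number())) |>
    select("scaffold", "start", "end", "strand", "gene_id", "family")
  list(genes = genes, cluster_truth = cluster_truth)
}

#' Simulate sex-specific read placements
#'
#' Places fixed-length single-end reads uniformly on each scaffold with a
#' Poisson-distributed count whose expectation is
#' `copy_number * mean_depth * length / (2 * read_length)`, where copy number
#' is 2 for autosomes in both sexes and for X in females, and 1 for X in males
#' (XO males carry a single X and no Y). With this convention `mean_depth` is
#' the realized per-base depth of any two-copy region, and the male X runs at
#' half of it — the twofold female:male contrast the sex scan detects.
#'
#' @param genome A `genome_model` from [simulate_genome()].
#' @param sample_sex `"female"` (XX) or `"male"` (XO).
#' @param mean_depth Target per-base fold-coverage of two-copy regions (> 0).
#' @param read_length Read length in bp (>= 1, <= shortest scaffold).
#' @param seed Integer seed.
#' @return A `read_placements` list: `placements` tibble
#'   (`scaffold`, `start`, `read_length`; 0-based starts), `sample_sex`,
#'   `total_reads`, `seed`.
#' @export
simulate_reads <- function(genome, sample_sex, mean_depth = 20,
                           read_length = 100, seed = 1) {
  stopifnot(inherits(genome, "genome_model"))
  sample_sex <- match.arg(sample_sex, c("female", "male"))
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    abort("mean_depth must be > 0")
  }
  if (read_length < 1 || read_length > min(genome$scaffolds$length)) {
    abort("read_length must be >= 1 and <= the shortest scaffold length")
  }
  withr::local_seed(as.integer(seed))
  sc <- genome$scaffolds
  copy <- ifelse(sc$is_x & sample_sex == "male", 1, 2)
  expected <- copy * mean_depth * sc$length / (2 * read_length)
  counts <- rpois(nrow(sc), expected)
  placements <- purrr::map_dfr(seq_len(nrow(sc)), function(i) {
    n <- counts[i]
    if (n == 0) return(NULL)
    tibble(scaffold = sc$name[i],
           start = floor(runif(n, 0, sc$length[i] - read_length + 1)))
  })
  if (nrow(placements) == 0) {
    placements <- tibble(scaffold = character(0), start = numeric(0))
  }
  placements$read_length <- rep(as.integer(read_length), nrow(placements))
  structure(list(placements = placements, sample_sex = sample_sex,
                 total_reads = nrow(placements), seed = as.integer(seed)),
            class = "read_placements")
}

#' @export
print.read_placements <- function(x, ...) {
  cat("<read_placements> ", x$sample_sex, ", ",
      format(x$total_reads, big.mark = ","), " reads of ",
      x$placements$read_length[1] %||% NA, " bp (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Simulate a one-to-one ortholog table with known ancestry
#'
#' Draws ortholog positions within each focal scaffold as a Poisson process at
#' `n_per_mb`, labels each pair with the reference chromosome assigned to its
#' position by the fusion map (positions covered by no fusion interval get
#' reference label `"none"`, emulating no-synteny regions), then removes a
#' `dropout` fraction of pairs at random. Focal and reference gene ids are
#' unique, so the table is one-to-one by construction.
#'
#' @param genome A `genome_model`.
#' @param fusion_map Fusion map tibble; defaults to the genome's own.
#' @param n_per_mb Expected ortholog pairs per Mb.
#' @param dropout Fraction of pairs removed at random, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A tibble of ortholog pairs: `focal_gene`, `focal_scaffold`,
#'   `focal_start` (0-based bp), `ref_gene`, `ref_chromosome`.
#' @export
simulate_orthologs <- function(genome, fusion_map = NULL, n_per_mb = 20,
                               dropout = 0.5, seed = 1) {
  stopifnot(inherits(genome, "genome_model"))
  if (is.null(fusion_map)) fusion_map <- genome$fusion_map
  if (dropout < 0 || dropout >= 1) abort("dropout must be in [0, 1)")
  withr::local_seed(as.integer(seed))
  sc <- genome$scaffolds
  pairs <- purrr::map_dfr(seq_len(nrow(sc)), function(i) {
    n <- rpois(1L, n_per_mb * sc$length[i] / 1e6)
    if (n == 0) return(NULL)
    tibble(focal_scaffold = sc$name[i],
           focal_start = sort(floor(runif(n, 0, sc$length[i]))))
  })
  if (nrow(pairs) == 0) {
    return(tibble(focal_gene = character(0), focal_scaffold = character(0),
                  focal_start = numeric(0), ref_gene = character(0),
                  ref_chromosome = character(0)))
  }
  pairs$ref_chromosome <- assign_fusion_label(
    pairs$focal_scaffold, pairs$focal_start, fusion_map)
  pairs <- pairs |>
    mutate(focal_gene = sprintf("foc%05d", row_number()),
           ref_gene = sprintf("ref%05d", row_number()))
  if (dropout > 0) {
    keep <- rbinom(nrow(pairs), 1L, 1 - dropout) == 1L
    pairs <- pairs[keep, , drop = FALSE]
  }
  pairs |>
    select("focal_gene", "focal_scaffold", "focal_start",
           "ref_gene", "ref_chromosome")
}

assign_fusion_label <- function(scaffold, position, fusion_map) {
  lab <- rep("none", length(scaffold))
  for (j in seq_len(nrow(fusion_map))) {
    fm <- fusion_map[j, ]
    hit <- scaffold == fm$focal_scaffold &
      position >= fm$start & position < fm$end
    lab[hit] <- fm$ref_chromosome
  }
  lab
}
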