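test_that("sliding GC handles periodic, ambiguous and empty sequences", {
  periodic <- strrep("ATGC", 25000) # 100 kb
  gc <- gc_sliding(periodic, window_size = 1e4, step = 1e3)
  expect_true(all(abs(gc$gc - 0.5) < 1e-12))
  allN <- strrep("N", 5000)
  gcn <- gc_sliding(allN, window_size = 1000, step = 1000)
  expect_true(all(is.na(gcn$gc)))
  expect_true(all(gcn$n_valid == 0))
  expect_equal(nrow(gc_sliding("", 100, 10)), 0)
  # soft-masked bases count as their base identity
  expect_equal(gc_sliding("acgt", 4, 4)$gc, 0.5)
})

test_that("sliding GC matches a brute-force scan with truncated tails", {
  seq_chr <- random_dna(20000, seed = 31)
  gc <- gc_sliding(seq_chr, window_size = 5000, step = 500)
  expect_equal(gc$gc, oracle_gc_windows(seq_chr, 5000, 500))
  expect_equal(nrow(gc), length(seq(0, 19999, by = 500)))
  # trailing windows are retained, flagged by their valid-base count
  expect_lt(gc$n_valid[nrow(gc)], 5000)
})

test_that("GC is strand-symmetric on full windows", {
  seq_chr <- random_dna(20000, seed = 32)
  fwd <- gc_sliding(seq_chr, window_size = 5000, step = 500)
  rev <- gc_sliding(revcomp_chr(seq_chr), window_size = 5000, step = 500)
  full_f <- fwd[fwd$end - fwd$start == 5000, ]
  full_r <- rev[rev$end - rev$start == 5000, ]
  # window [i, i+w) maps to [L-i-w, L-i) on the reverse complement
  expect_equal(full_f$gc,
               full_r$gc[match(20000 - full_f$start - 5000, full_r$start)])
})

test_that("feature density counts each feature once at its anchor", {
  grid <- make_windows(c(s1 = 3e5), 1e5)
  genes <- tibble::tibble(scaffold = "s1",
                          start = c(1000, 2000, 3000, 99950),
                          end = c(1500, 2500, 3500, 100400))
  d <- feature_density(genes, grid)
  expect_equal(d$count, c(4L, 0L, 0L)) # boundary gene counted at its start
  dm <- feature_density(genes, grid, anchor = "midpoint")
  expect_equal(dm$count, c(3L, 1L, 0L))
  expect_error(feature_density(
    tibble::tibble(scaffold = "nope", start = 1, end = 2), grid), "nope")
})

test_that("uniform features give Poisson-consistent, conserved counts", {
  grid <- make_windows(c(s1 = 1e6), 1e5)
  genes <- random_genes(1000, 1e6, seed = 33, gene_len_max = 100)
  d <- feature_density(genes, grid)
  expect_equal(sum(d$count), 1000L)
  gof <- suppressWarnings(stats::chisq.test(d$count))
  expect_gt(gof$p.value, 0.001)
})

test_that("n50 matches its definition on printed and random cases", {
  expect_equal(n50(10), 10)
  expect_equal(n50(c(5, 4, 3, 2, 1)), 4)
  expect_equal(n50(c(2, 2, 2, 2)), 2)
  expect_error(n50(numeric(0)), "empty")
  expect_error(n50(c(3, 0)), "positive")
  withr::with_seed(34, {
    for (i in 1:200) {
      lens <- sample(1:50, sample(1:8, 1), replace = TRUE)
      expect_equal(n50(lens), oracle_n50(lens))
    }
  })
})

test_that("assembly stats summarise lengths and GC", {
  seqs <- Biostrings::DNAStringSet(c(a = "ACGTN", b = "GGGGGGGGGG"))
  st <- assembly_stats(seqs)
  expect_equal(st$n_scaffolds, 2)
  expect_equal(st$total_length, 15)
  expect_equal(st$largest, 10)
  expect_equal(st$n50, 10)
  # N excluded from the GC denominator: (2 + 10) / 14
  expect_equal(st$global_gc, 12 / 14)
  expect_true(is.na(assembly_stats(c(5, 3))$global_gc))
})

test_that("completeness arithmetic reports both precisions", {
  cp <- completeness_percent(854, 982)
  expect_equal(cp$percent_rounded, 87)
  expect_equal(cp$percent, 100 * 854 / 982)
  expect_equal(completeness_percent(0, 10)$percent, 0)
  expect_equal(completeness_percent(10, 10)$percent, 100)
  expect_error(completeness_percent(1, 0), "total")
  expect_error(completeness_percent(5, 4), "found")
})

test_that("cluster sweep joins nearby genes and honours min_size", {
  genes <- tibble::tibble(scaffold = "s1",
                          start = c(1000, 2000, 3000, 500000),
                          end = c(1001, 2001, 3001, 500001),
                          gene_id = paste0("g", 1:4))
  cl <- find_clusters(genes, max_gap = 10000, min_size = 2)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$gene_ids, "g1,g2,g3")
  expect_equal(cl$start, 1000)
  expect_equal(cl$end, 3001)
  # overlapping genes always cluster (gap floored at 0)
  ov <- tibble::tibble(scaffold = "s1", start = c(0, 50, 120),
                       end = c(100, 150, 200), gene_id = paste0("g", 1:3))
  expect_equal(find_clusters(ov, max_gap = 0, min_size = 3)$n_genes, 3L)
})

test_that("cluster sweep equals transitive-closure clustering", {
  for (seed in 41:45) {
    genes <- random_genes(40, 2e5, seed = seed)
    cl <- find_clusters(genes, max_gap = 3000, min_size = 2)
    oracle <- oracle_cluster_partition(genes, 3000)
    oracle <- Filter(function(x) length(x) >= 2, oracle)
    got <- lapply(strsplit(cl$gene_ids, ","), sort)
    want <- lapply(oracle, function(x) sort(as.character(x)))
    expect_setequal(got, want)
  }
})

test_that("planted tandem clusters are recovered", {
  g <- simulate_genome(default_scaffold_specs(), seed = 46,
                       genes_per_mb = 5, cluster_families = 2,
                       cluster_size = 5, cluster_gap = 2000,
                       sequences = FALSE)
  cl <- find_clusters(g$genes, max_gap = 10000, min_size = 3)
  for (i in seq_len(nrow(g$cluster_truth))) {
    tr <- g$cluster_truth[i, ]
    hit <- cl$scaffold == tr$scaffold & cl$start <= tr$start &
      cl$end >= tr$end
    expect_true(any(hit))
  }
})

test_that("X-scaffold repeats are arm-enriched in the default genome", {
  g <- toy_genome(seed = 47)
  x <- g$scaffolds[g$scaffolds$is_x, ]
  grid <- make_windows(stats::setNames(x$length, x$name), 1e5)
  d <- feature_density(g$repeats[g$repeats$scaffold == x$name, ], grid)
  arm <- floor(x$length * x$arm_fraction)
  in_arm <- d$start < arm | d$end > x$length - arm
  expect_gt(mean(d$count[in_arm]), mean(d$count[!in_arm]))
})
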