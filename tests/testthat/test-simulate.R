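test_that("simulated sequence GC matches its generating probability", {
  specs <- scaffold_spec("s1", 1e5, gc_center = 0.5, gc_arms = 0.5)
  g <- simulate_genome(specs, seed = 11, genes_per_mb = 0,
                       cluster_families = 0)
  freq <- Biostrings::alphabetFrequency(g$sequences)[1, c("A", "C", "G", "T")]
  gc <- sum(freq[c("C", "G")]) / sum(freq)
  # binomial standard error at p = 0.5 over 1e5 draws
  expect_lt(abs(gc - 0.5), 5 * sqrt(0.25 / 1e5))
})

test_that("degenerate GC probabilities produce pure arm/centre composition", {
  specs <- scaffold_spec("s1", 1e5, gc_center = 1, gc_arms = 0,
                         arm_fraction = 0.25)
  g <- simulate_genome(specs, seed = 1, genes_per_mb = 0,
                       cluster_families = 0)
  s <- as.character(g$sequences[[1]])
  first_quarter <- substr(s, 1, 25000)
  centre <- substr(s, 25001, 75000)
  expect_false(grepl("[GC]", first_quarter))
  expect_false(grepl("[AT]", centre))
})

test_that("identical specs and seed give byte-identical FASTA", {
  specs <- default_scaffold_specs()[1:2, ]
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_genome_fasta(simulate_genome(specs, seed = 7)$sequences, f1)
  write_genome_fasta(simulate_genome(specs, seed = 7)$sequences, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("invalid scaffold specs are rejected with the offending name", {
  expect_error(scaffold_spec("bad_len", 0), "bad_len")
  specs <- default_scaffold_specs()
  specs$repeat_rate_arms[2] <- -1
  expect_error(simulate_genome(specs), specs$name[2])
  expect_error(scaffold_spec("bad_gc", 100, gc_center = 1.2), "bad_gc")
})

test_that("read counts follow the Poisson copy-number model", {
  g <- one_scaffold_genome(1e6)
  r <- simulate_reads(g, "female", mean_depth = 20, read_length = 100,
                      seed = 5)
  expected <- 2 * 20 * 1e6 / (2 * 100)
  expect_lt(abs(r$total_reads - expected), 5 * sqrt(expected))
  expect_equal(r$total_reads, nrow(r$placements))
  expect_true(all(r$placements$start >= 0 &
                    r$placements$start + 100 <= 1e6))
})

test_that("male X runs at half the autosomal per-base depth", {
  specs <- dplyr::bind_rows(scaffold_spec("chrX", 1e6, is_x = TRUE),
                            scaffold_spec("chrA", 1e6))
  g <- simulate_genome(specs, seed = 2, genes_per_mb = 0,
                       cluster_families = 0, sequences = FALSE)
  r <- simulate_reads(g, "male", mean_depth = 20, read_length = 100,
                      seed = 3)
  depth <- r$placements |>
    dplyr::count(scaffold) |>
    dplyr::mutate(depth = n * 100 / 1e6)
  ratio <- depth$depth[depth$scaffold == "chrX"] /
    depth$depth[depth$scaffold == "chrA"]
  expect_lt(abs(ratio - 0.5), 0.05)
  rf <- simulate_reads(g, "female", mean_depth = 20, read_length = 100,
                       seed = 3)
  nf <- dplyr::count(rf$placements, scaffold)
  # females carry two X copies: no sex difference in expectation
  expect_lt(abs(nf$n[nf$scaffold == "chrX"] / nf$n[nf$scaffold == "chrA"] - 1),
            0.05)
})

test_that("degenerate read parameters are rejected", {
  g <- one_scaffold_genome(1e5)
  expect_error(simulate_reads(g, "female", mean_depth = 0), "mean_depth")
  expect_error(simulate_reads(g, "neuter"), "arg")
  expect_error(simulate_reads(g, "male", read_length = 1e6 + 1),
               "read_length")
})

test_that("copy-number contract holds across seeds", {
  # across 20 seeds at 10x, male X:autosome depth ratio stays in [0.4, 0.6]
  g <- toy_genome(seed = 1)
  ratios <- vapply(1:20, function(s) {
    r <- simulate_reads(g, "male", mean_depth = 10, read_length = 100,
                        seed = s)
    d <- r$placements |>
      dplyr::count(scaffold) |>
      dplyr::left_join(tibble::tibble(scaffold = g$scaffolds$name,
                                      len = g$scaffolds$length),
                       by = "scaffold") |>
      dplyr::mutate(depth = n * 100 / len)
    x <- d$depth[d$scaffold %in% g$truth_x]
    a <- mean(d$depth[!d$scaffold %in% g$truth_x])
    x / a
  }, numeric(1))
  expect_true(all(ratios > 0.4 & ratios < 0.6))
})

test_that("ortholog labels follow the fusion map", {
  g <- one_scaffold_genome(2e6)
  fm <- tibble::tibble(focal_scaffold = "s1", start = 0, end = 2e6,
                       ref_chromosome = "II")
  orth <- simulate_orthologs(g, fm, n_per_mb = 50, dropout = 0, seed = 4)
  expect_true(all(orth$ref_chromosome == "II"))
  # uncovered positions get the no-synteny label rather than an error
  fm_gap <- tibble::tibble(focal_scaffold = "s1", start = 0, end = 1e6,
                           ref_chromosome = "II")
  orth2 <- simulate_orthologs(g, fm_gap, n_per_mb = 50, dropout = 0,
                              seed = 4)
  expect_setequal(unique(orth2$ref_chromosome), c("II", "none"))
  expect_true(all(orth2$focal_start[orth2$ref_chromosome == "none"] >= 1e6))
})

test_that("fused-scaffold ortholog composition matches segment lengths", {
  # 10 Mb of chrII ancestry followed by 7.5 Mb of chrIV ancestry
  g <- one_scaffold_genome(17.5e6)
  fm <- tibble::tibble(focal_scaffold = "s1", start = c(0, 10e6),
                       end = c(10e6, 17.5e6),
                       ref_chromosome = c("II", "IV"))
  orth <- simulate_orthologs(g, fm, n_per_mb = 100, dropout = 0, seed = 8)
  p_hat <- mean(orth$ref_chromosome == "II")
  p <- 10 / 17.5
  expect_lt(abs(p_hat - p), 5 * sqrt(p * (1 - p) / nrow(orth)))
})

test_that("dropout removes the expected fraction and keeps one-to-one", {
  g <- one_scaffold_genome(10e6)
  fm <- tibble::tibble(focal_scaffold = "s1", start = 0, end = 10e6,
                       ref_chromosome = "II")
  full <- simulate_orthologs(g, fm, n_per_mb = 100, dropout = 0, seed = 9)
  half <- simulate_orthologs(g, fm, n_per_mb = 100, dropout = 0.5, seed = 9)
  n <- nrow(full)
  expect_lt(abs(nrow(half) - n / 2), 5 * sqrt(n * 0.25))
  expect_false(any(duplicated(half$focal_gene)))
  expect_false(any(duplicated(half$ref_gene)))
  expect_error(simulate_orthologs(g, fm, dropout = 1), "dropout")
})
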