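test_that("make_windows tiles scaffolds exactly", {
  g <- make_windows(c(s1 = 250000), 100000)
  expect_equal(g$start, c(0, 100000, 200000))
  expect_equal(g$end, c(100000, 200000, 250000))
  expect_equal(make_windows(c(s1 = 100000), 100000)$end, 100000)
  tiny <- make_windows(c(s1 = 1), 100000)
  expect_equal(nrow(tiny), 1)
  expect_equal(tiny$end, 1)
  expect_error(make_windows(c(s1 = 0), 1e5), "s1")
  expect_error(make_windows(c(s1 = 10), 0), "window_size")
})

test_that("coverage attributes single reads exactly, pro rata at boundaries", {
  grid <- make_windows(c(s1 = 3e5), 1e5)
  inside <- tibble::tibble(scaffold = "s1", start = 1000, read_length = 100L)
  tr <- coverage_from_placements(inside, grid)
  expect_equal(tr$depth, c(0.001, 0, 0))
  # read straddling the first boundary 60/40
  strad <- tibble::tibble(scaffold = "s1", start = 1e5 - 60,
                          read_length = 100L)
  tr2 <- coverage_from_placements(strad, grid)
  expect_equal(tr2$depth * 1e5, c(60, 40, 0))
})

test_that("attributed bases are conserved exactly", {
  g <- toy_genome(seed = 3)
  r <- simulate_reads(g, "female", mean_depth = 2, read_length = 100,
                      seed = 4)
  grid <- make_windows(g, 1e5)
  tr <- coverage_from_placements(r, grid)
  expect_equal(sum(tr$depth * (tr$end - tr$start)),
               r$total_reads * 100)
  expect_equal(attr(tr, "library_size"), r$total_reads * 100)
})

test_that("SAM alignments reproduce placement coverage and honour MAPQ", {
  g <- toy_genome(seed = 5)
  r <- simulate_reads(g, "male", mean_depth = 1, read_length = 100, seed = 6)
  sam <- tempfile(fileext = ".sam")
  write_sam(r, g, sam)
  grid <- make_windows(g, 1e5)
  from_sam <- coverage_from_alignments(sam, grid)
  from_pl <- coverage_from_placements(r, grid)
  expect_equal(from_sam$depth, from_pl$depth)
  # all records carry MAPQ 60: a higher threshold drops everything
  expect_warning(empty <- coverage_from_alignments(sam, grid, min_mapq = 61),
                 "no usable")
  expect_true(all(empty$depth == 0))
  # alignments to a scaffold missing from the grid are an error by name
  grid_part <- make_windows(c(scf_X = 3.5e6), 1e5)
  expect_error(coverage_from_alignments(sam, grid_part), "scf_1")
})

test_that("bedgraph coverage averages by overlap length", {
  grid <- make_windows(c(s1 = 2e5), 1e5)
  const <- tibble::tibble(scaffold = "s1", start = c(0, 1e5),
                          end = c(1e5, 2e5), depth = 7)
  expect_equal(coverage_from_bedgraph(const, grid)$depth, c(7, 7))
  half <- tibble::tibble(scaffold = "s1", start = 0, end = 5e4, depth = 10)
  expect_equal(coverage_from_bedgraph(half, grid)$depth, c(5, 0))
  overlapping <- tibble::tibble(scaffold = "s1", start = c(0, 100),
                                end = c(200, 300), depth = 1)
  expect_error(coverage_from_bedgraph(overlapping, grid), "overlap")
})

test_that("a coverage track survives a BEDGRAPH round trip", {
  g <- toy_genome(seed = 7)
  r <- simulate_reads(g, "female", mean_depth = 3, read_length = 100,
                      seed = 8)
  grid <- make_windows(g, 1e5)
  tr <- coverage_from_placements(r, grid)
  bg <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, bg)
  back <- coverage_from_bedgraph(bg, grid)
  expect_equal(back$depth, tr$depth)
})

test_that("median normalization fixes the median at 1 and is scale-free", {
  grid <- make_windows(c(s1 = 5e5), 1e5)
  tr <- grid
  tr$depth <- c(10, 20, 20, 30, 40)
  norm <- normalize_track(tr)
  expect_equal(median(norm$depth), 1)
  expect_equal(norm$depth, tr$depth / 20)
  tr10 <- tr
  tr10$depth <- tr$depth * 10
  expect_equal(normalize_track(tr10)$depth, norm$depth)
  zero <- grid
  zero$depth <- 0
  expect_error(normalize_pair(zero, tr), "normalize")
})

test_that("samples sequenced at different depths normalize together", {
  g <- toy_genome(seed = 9)
  grid <- make_windows(g, 1e5)
  f <- coverage_from_placements(simulate_reads(g, "female", 20, 100, 10),
                                grid)
  m <- coverage_from_placements(simulate_reads(g, "male", 35, 100, 11),
                                grid)
  norm <- normalize_pair(f, m)
  auto <- !grid$scaffold %in% g$truth_x
  rel_diff <- (norm$female$depth[auto] - norm$male$depth[auto]) /
    norm$male$depth[auto]
  expect_lt(max(abs(rel_diff)), 0.1)
  expect_lt(abs(mean(rel_diff)), 0.01)
})

test_that("ratio track arithmetic and masking rules", {
  grid <- make_windows(c(s1 = 3e5), 1e5)
  f <- grid; f$depth <- c(2, 1, 1); f$depth_raw <- f$depth
  m <- grid; m$depth <- c(1, 1, 0); m$depth_raw <- m$depth
  rt <- ratio_track(f, m)
  expect_equal(rt$log2_ratio[1], 1)
  expect_equal(rt$log2_ratio[2], 0)
  expect_true(rt$masked[3])
  expect_true(is.na(rt$log2_ratio[3]))
})

test_that("swapping the sexes negates every unmasked ratio exactly", {
  g <- toy_genome(seed = 12)
  grid <- make_windows(g, 1e5)
  f <- coverage_from_placements(simulate_reads(g, "female", 10, 100, 13),
                                grid)
  m <- coverage_from_placements(simulate_reads(g, "male", 10, 100, 14), grid)
  n1 <- normalize_pair(f, m)
  n2 <- normalize_pair(m, f)
  r1 <- ratio_track(n1$female, n1$male)
  r2 <- ratio_track(n2$female, n2$male)
  expect_equal(r2$log2_ratio[!r2$masked], -r1$log2_ratio[!r1$masked])
})

test_that("scaffold calls recover the planted X and respect the bands", {
  g <- toy_genome(seed = 15)
  scan <- scan_sex_chromosomes(simulate_reads(g, "female", 20, 100, 16),
                               simulate_reads(g, "male", 20, 100, 17), g)
  calls <- tidy(scan)
  expect_equal(calls$call[calls$scaffold %in% g$truth_x], "X-linked")
  expect_true(all(calls$call[!calls$scaffold %in% g$truth_x] == "autosomal"))
  expect_equal(glance(scan)$n_x_linked, 1)
})

test_that("identical samples give an all-autosomal null", {
  g <- toy_genome(seed = 18)
  r <- simulate_reads(g, "female", 10, 100, 19)
  scan <- scan_sex_chromosomes(r, r, g)
  expect_true(all(tidy(scan)$call == "autosomal"))
  expect_true(all(abs(tidy(scan)$median_log2_ratio) < 1e-12))
})

test_that("even-count medians use the midpoint convention", {
  ratio <- tibble::tibble(scaffold = "s2", start = c(0, 1e5),
                          end = c(1e5, 2e5), window = 0:1,
                          depth_f = 1, depth_m = 1,
                          depth_raw_f = 1, depth_raw_m = 1,
                          log2_ratio = c(0.5, 0.9), masked = FALSE)
  calls <- call_scaffolds(ratio)
  # midpoint (0.5 + 0.9)/2 = 0.7 lies inside the X band
  expect_equal(calls$median_log2_ratio, 0.7)
  expect_equal(calls$call, "X-linked")
})

test_that("library scaling never changes a call", {
  g <- toy_genome(seed = 20)
  grid <- make_windows(g, 1e5)
  f <- coverage_from_placements(simulate_reads(g, "female", 10, 100, 21),
                                grid)
  m <- coverage_from_placements(simulate_reads(g, "male", 10, 100, 22), grid)
  base_calls <- call_scaffolds(ratio_track(normalize_pair(f, m)$female,
                                           normalize_pair(f, m)$male))
  for (k in c(0.01, 13, 1000)) {
    fk <- f; fk$depth <- f$depth * k
    n <- normalize_pair(fk, m)
    calls <- call_scaffolds(ratio_track(n$female, n$male))
    expect_equal(calls$call, base_calls$call)
  }
})
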