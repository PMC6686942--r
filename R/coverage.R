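#' Windowed coverage from simulated read placements
#'
#' Attributes every read base to the window containing it; a read spanning a
#' window boundary contributes to both windows pro rata by overlap, so total
#' attributed bases equal `total_reads * read_length` exactly.
#'
#' @param placements A `read_placements` object from [simulate_reads()], or a
#'   tibble with columns `scaffold`, `start` (0-based), `read_length`.
#' @param grid Window grid from [make_windows()].
#' @param sample_label Label stored on the track (defaults to the placement
#'   set's `sample_sex` when available).
#' @return A coverage track: the grid tibble plus a `depth` column (mean
#'   per-base depth, attributed bases / window length), with attributes
#'   `sample_label` and `library_size` (total attributed bases).
#' @export
coverage_from_placements <- function(placements, grid, sample_label = NULL) {
  if (inherits(placements, "read_placements")) {
    if (is.null(sample_label)) sample_label <- placements$sample_sex
    placements <- placements$placements
  }
  stopifnot(is.data.frame(placements))
  if (nrow(placements) == 0) {
    warn("no read placements; returning an all-zero coverage track")
    return(new_coverage_track(grid, rep(0, nrow(grid)),
                              sample_label %||% "unknown", 0))
  }
  unknown <- setdiff(unique(placements$scaffold), unique(grid$scaffold))
  if (length(unknown) > 0) {
    abort(paste0("placements on scaffold(s) absent from the grid: ",
                 paste(unknown, collapse = ", ")))
  }
  bases <- attribute_bases(placements$scaffold, placements$start,
                           placements$read_length, grid)
  new_coverage_track(grid, bases / (grid$end - grid$start),
                     sample_label %||% "unknown", sum(bases))
}

#' Windowed coverage from SAM/BAM alignments
#'
#' Reads mapped records (skipping unmapped and sub-`min_mapq` alignments) and
#' attributes each reference-aligned base to the window containing it, pro
#' rata across window boundaries.
#'
#' @param path Path to a SAM or BAM file.
#' @param grid Window grid from [make_windows()]; alignment reference names
#'   must be a subset of its scaffolds.
#' @param min_mapq Minimum mapping quality (records with unavailable MAPQ are
#'   kept when `min_mapq` is 0).
#' @param sample_label Label stored on the track.
#' @return A coverage track (see [coverage_from_placements()]).
#' @export
coverage_from_alignments <- function(path, grid, min_mapq = 0,
                                     sample_label = NULL) {
  stopifnot(file.exists(path), min_mapq >= 0)
  if (is.null(sample_label)) {
    sample_label <- sub("\\.(sam|bam)$", "", basename(path))
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  aln <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = "mapq"))
  mapq <- S4Vectors::mcols(aln)$mapq
  keep <- is.na(mapq) | mapq >= min_mapq
  if (min_mapq > 0) keep <- !is.na(mapq) & mapq >= min_mapq
  aln <- aln[keep]
  if (length(aln) == 0) {
    warn("no usable alignments; returning an all-zero coverage track")
    return(new_coverage_track(grid, rep(0, nrow(grid)), sample_label, 0))
  }
  scaff <- as.character(GenomicAlignments::seqnames(aln))
  unknown <- setdiff(unique(scaff), unique(grid$scaffold))
  if (length(unknown) > 0) {
    abort(paste0("alignments to scaffold(s) absent from the grid: ",
                 paste(unknown, collapse = ", ")))
  }
  start0 <- GenomicAlignments::start(aln) - 1
  width <- GenomicAlignments::width(aln)
  bases <- attribute_bases(scaff, start0, width, grid)
  new_coverage_track(grid, bases / (grid$end - grid$start), sample_label,
                     sum(bases))
}

#' Windowed coverage from a BEDGRAPH depth track
#'
#' Window value is the length-weighted mean of interval depths overlapping
#' the window; positions covered by no interval count as depth 0.
#'
#' @param bedgraph Path to a BEDGRAPH file (0-based half-open; `track` and
#'   comment lines ignored) or a tibble with columns `scaffold`, `start`,
#'   `end`, `depth`. Intervals must not overlap within a scaffold.
#' @param grid Window grid from [make_windows()].
#' @param sample_label Label stored on the track.
#' @return A coverage track (see [coverage_from_placements()]).
#' @export
coverage_from_bedgraph <- function(bedgraph, grid, sample_label = NULL) {
  if (is.character(bedgraph)) {
    if (is.null(sample_label)) {
      sample_label <- sub("\\.(bedgraph|bdg|bg)$", "", basename(bedgraph))
    }
    bedgraph <- read_bedgraph(bedgraph)
  }
  stopifnot(is.data.frame(bedgraph),
            all(c("scaffold", "start", "end", "depth") %in% names(bedgraph)))
  bg <- arrange(bedgraph, .data$scaffold, .data$start)
  same <- bg$scaffold[-1] == bg$scaffold[-nrow(bg)]
  if (nrow(bg) > 1 && any(same & bg$start[-1] < bg$end[-nrow(bg)])) {
    abort("overlapping BEDGRAPH intervals within a scaffold")
  }
  unknown <- setdiff(unique(bg$scaffold), unique(grid$scaffold))
  if (length(unknown) > 0) {
    abort(paste0("BEDGRAPH intervals on scaffold(s) absent from the grid: ",
                 paste(unknown, collapse = ", ")))
  }
  gr_b <- GenomicRanges::GRanges(bg$scaffold,
                                 IRanges::IRanges(bg$start + 1, bg$end))
  gr_w <- GenomicRanges::GRanges(grid$scaffold,
                                 IRanges::IRanges(grid$start + 1, grid$end))
  hits <- GenomicRanges::findOverlaps(gr_b, gr_w)
  ov <- IRanges::width(IRanges::pintersect(
    gr_b[S4Vectors::queryHits(hits)], gr_w[S4Vectors::subjectHits(hits)]))
  bases <- base_sum_by_window(S4Vectors::subjectHits(hits),
                              ov * bg$depth[S4Vectors::queryHits(hits)],
                              nrow(grid))
  new_coverage_track(grid, bases / (grid$end - grid$start),
                     sample_label %||% "bedgraph", sum(bases))
}

# Pro-rata attribution of interval bases to grid windows (0-based half-open).
attribute_bases <- function(scaffold, start0, width, grid) {
  gr_r <- GenomicRanges::GRanges(scaffold,
                                 IRanges::IRanges(start0 + 1, width = width))
  gr_w <- GenomicRanges::GRanges(grid$scaffold,
                                 IRanges::IRanges(grid$start + 1, grid$end))
  hits <- GenomicRanges::findOverlaps(gr_r, gr_w)
  ov <- IRanges::width(IRanges::pintersect(
    gr_r[S4Vectors::queryHits(hits)], gr_w[S4Vectors::subjectHits(hits)]))
  base_sum_by_window(S4Vectors::subjectHits(hits), ov, nrow(grid))
}

base_sum_by_window <- function(window_idx, contribution, n_windows) {
  out <- numeric(n_windows)
  agg <- rowsum(contribution, window_idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

new_coverage_track <- function(grid, depth, sample_label, library_size) {
  track <- as_tibble(grid)
  track$depth <- depth
  attr(track, "window_size") <- attr(grid, "window_size")
  attr(track, "sample_label") <- sample_label
  attr(track, "library_size") <- library_size
  track
}

#' Median-scale a female/male coverage-track pair
#'
#' Divides each track's depths by that track's own median window depth, so
#' each sample's median window becomes 1. The median is robust to the X
#' minority of windows, and the result is invariant to scaling either input
#' library by any positive constant. Raw depths are retained in `depth_raw`
#' for downstream masking.
#'
#' @param female,male Coverage tracks on the same grid.
#' @return A list with elements `female` and `male`: tracks with normalized
#'   `depth` and original `depth_raw`.
#' @export
normalize_pair <- function(female, male) {
  check_same_grid(female, male)
  list(female = normalize_track(female), male = normalize_track(male))
}

normalize_track <- function(track) {
  med <- median(track$depth)
  if (!is.finite(med) || med <= 0) {
    abort(paste0("cannot normalize track '",
                 attr(track, "sample_label") %||% "?",
                 "': median window depth is not positive"))
  }
  track$depth_raw <- track$depth
  track$depth <- track$depth / med
  track
}

check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !all(a$scaffold == b$scaffold & a$start == b$start & a$end == b$end)) {
    abort("the two tracks are not on the same window grid")
  }
  invisible(TRUE)
}

#' Per-window log2 female:male depth-ratio track
#'
#' Forms `log2(female / male)` per window from normalized depths. Windows
#' where either sample's raw depth is zero, or below `min_depth`, are masked:
#' they carry `NA` instead of a ratio. Swapping the two samples negates every
#' unmasked ratio exactly.
#'
#' @param female,male Normalized coverage tracks from [normalize_pair()]
#'   (tracks without a `depth_raw` column are treated as raw).
#' @param min_depth Raw mean-depth threshold below which a window is masked;
#'   the default 0 masks exactly the windows with no coverage in one sample.
#' @return A ratio-track tibble: grid columns plus `depth_f`, `depth_m`
#'   (normalized), `depth_raw_f`, `depth_raw_m`, `log2_ratio`, `masked`.
#' @export
ratio_track <- function(female, male, min_depth = 0) {
  check_same_grid(female, male)
  raw_f <- female$depth_raw %||% female$depth
  raw_m <- male$depth_raw %||% male$depth
  masked <- raw_f <= 0 | raw_m <= 0 | raw_f < min_depth | raw_m < min_depth
  ratio <- ifelse(masked, NA_real_, log2(female$depth / male$depth))
  out <- as_tibble(female[c("scaffold", "start", "end", "window")])
  out$depth_f <- female$depth
  out$depth_m <- male$depth
  out$depth_raw_f <- raw_f
  out$depth_raw_m <- raw_m
  out$log2_ratio <- ratio
  out$masked <- masked
  attr(out, "window_size") <- attr(female, "window_size")
  out
}

#' Call scaffolds X-linked or autosomal from a ratio track
#'
#' Summarises each scaffold by the median of its unmasked per-window
#' log2(female/male) ratios (for an even number of windows the usual midpoint
#' of the two central values). A scaffold is called `X-linked` when the
#' median falls in `x_band` (default `[0.6, 1.4]`, centred on the twofold
#' log2 ratio of 1), `autosomal` when it falls in `autosome_band` (default
#' `[-0.4, 0.4]`), and `ambiguous` otherwise or when fewer than
#' `min_unmasked_fraction` of its windows are unmasked.
#'
#' @param ratio A ratio-track tibble from [ratio_track()].
#' @param x_band,autosome_band Closed log2-ratio intervals `c(low, high)`.
#' @param min_unmasked_fraction Minimum fraction of unmasked windows required
#'   for a non-ambiguous call.
#' @return A tibble: `scaffold`, `n_windows`, `n_unmasked`,
#'   `median_log2_ratio`, `call`.
#' @export
call_scaffolds <- function(ratio, x_band = c(0.6, 1.4),
                           autosome_band = c(-0.4, 0.4),
                           min_unmasked_fraction = 0.5) {
  stopifnot(x_band[1] < x_band[2], autosome_band[1] < autosome_band[2])
  ratio |>
    group_by(.data$scaffold) |>
    summarise(
      n_windows = n(),
      n_unmasked = sum(!.data$masked),
      median_log2_ratio = if (any(!.data$masked))
        median(.data$log2_ratio[!.data$masked]) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(call = dplyr::case_when(
      .data$n_unmasked == 0 ~ "ambiguous",
      .data$n_unmasked / .data$n_windows < min_unmasked_fraction ~ "ambiguous",
      .data$median_log2_ratio >= x_band[1] &
        .data$median_log2_ratio <= x_band[2] ~ "X-linked",
      .data$median_log2_ratio >= autosome_band[1] &
        .data$median_log2_ratio <= autosome_band[2] ~ "autosomal",
      TRUE ~ "ambiguous"
    ))
}

#' Sex-chromosome scan from female and male sequencing
#'
#' One-call wrapper around the coverage-ratio analysis: windowed depth for
#' each sample, per-sample median normalization, the log2(female/male) ratio
#' track, and per-scaffold X-linked/autosomal calls. X-linked scaffolds are
#' present in two copies in females (XX) but one in males (XO), so their
#' windows sit near log2 ratio 1 while autosomes sit near 0.
#'
#' @param female,male Each a `read_placements` object, a coverage track
#'   already on the right grid, or a path to a SAM/BAM (or `.bedgraph`) file.
#' @param scaffold_lengths Named lengths, a data frame, or a `genome_model`.
#' @param window_size Coverage window in bp (default 100,000).
#' @param min_mapq Minimum mapping quality for alignment input.
#' @param min_depth Raw-depth masking threshold (see [ratio_track()]).
#' @inheritParams call_scaffolds
#' @return A `sex_scan` object with elements `ratio` (per-window tibble),
#'   `calls` (per-scaffold tibble) and `params`; supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' g <- simulate_genome(seed = 1, sequences = FALSE)
#' scan <- scan_sex_chromosomes(
#'   simulate_reads(g, "female", seed = 2),
#'   simulate_reads(g, "male", seed = 3), g)
#' tidy(scan)
#' @export
scan_sex_chromosomes <- function(female, male, scaffold_lengths,
                                 window_size = 1e5, min_mapq = 0,
                                 min_depth = 0,
                                 x_band = c(0.6, 1.4),
                                 autosome_band = c(-0.4, 0.4),
                                 min_unmasked_fraction = 0.5) {
  grid <- make_windows(scaffold_lengths, window_size)
  f <- as_coverage_track(female, grid, min_mapq, "female")
  m <- as_coverage_track(male, grid, min_mapq, "male")
  norm <- normalize_pair(f, m)
  ratio <- ratio_track(norm$female, norm$male, min_depth = min_depth)
  calls <- call_scaffolds(ratio, x_band, autosome_band,
                          min_unmasked_fraction)
  lens <- attr(grid, "scaffold_lengths")
  calls <- calls |>
    mutate(length = as.numeric(lens[.data$scaffold])) |>
    arrange(desc(.data$length)) |>
    select("scaffold", "length", "n_windows", "n_unmasked",
           "median_log2_ratio", "call")
  structure(list(ratio = ratio, calls = calls,
                 params = list(window_size = window_size,
                               min_depth = min_depth, x_band = x_band,
                               autosome_band = autosome_band,
                               min_unmasked_fraction = min_unmasked_fraction)),
            class = "sex_scan")
}

as_coverage_track <- function(x, grid, min_mapq, label) {
  if (inherits(x, "read_placements")) {
    return(coverage_from_placements(x, grid, sample_label = label))
  }
  if (is.character(x) && length(x) == 1) {
    if (grepl("\\.(bedgraph|bdg|bg)$", x, ignore.case = TRUE)) {
      return(coverage_from_bedgraph(x, grid, sample_label = label))
    }
    return(coverage_from_alignments(x, grid, min_mapq, sample_label = label))
  }
  if (is.data.frame(x) && "depth" %in% names(x)) {
    check_same_grid(x, grid |> mutate(depth = 0))
    return(x)
  }
  abort("cannot interpret coverage input: need read placements, a track, or a SAM/BAM/BEDGRAPH path")
}

#' @export
print.sex_scan <- function(x, ...) {
  cat("<sex_scan> ", nrow(x$calls), " scaffolds, window ",
      format(x$params$window_size, big.mark = ","), " bp\n", sep = "")
  print(x$calls, ...)
  invisible(x)
}
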