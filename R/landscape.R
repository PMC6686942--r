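#' Sliding-window GC content
#'
#' Computes GC fraction in windows of `window_size` bp advancing by `step` bp
#' (defaults 100 kb / 1 kb, the standard genome-landscape parameters).
#' Windows start at 0, `step`, `2*step`, ... while the start lies within the
#' sequence; trailing windows are truncated rather than dropped, and carry
#' their valid-base count so short windows can be filtered downstream. GC is
#' `(G+C)/(A+C+G+T)` case-insensitively; Ns and other ambiguity codes are
#' excluded from the denominator, and a window with no valid base has
#' `gc = NA`.
#'
#' @param sequence A single nucleotide sequence: character string,
#'   [Biostrings::DNAString], or length-1 DNAStringSet.
#' @param window_size Window size in bp (>= `step`).
#' @param step Step between window starts in bp (>= 1).
#' @param scaffold Optional scaffold name recorded in the output.
#' @return A tibble: `scaffold`, `start`, `end` (0-based half-open), `gc`,
#'   `n_valid`.
#' @examples
#' gc_sliding(strrep("ATGC", 10), window_size = 8, step = 4)
#' @export
gc_sliding <- function(sequence, window_size = 1e5, step = 1e3,
                       scaffold = NA_character_) {
  stopifnot(step >= 1, window_size >= step)
  seq_chr <- as_sequence_string(sequence)
  len <- nchar(seq_chr)
  if (len == 0) {
    return(tibble(scaffold = character(0), start = numeric(0),
                  end = numeric(0), gc = numeric(0), n_valid = numeric(0)))
  }
  codes <- charToRaw(toupper(seq_chr))
  is_gc <- codes == charToRaw("G") | codes == charToRaw("C")
  is_valid <- is_gc | codes == charToRaw("A") | codes == charToRaw("T")
  cum_gc <- c(0, cumsum(is_gc))
  cum_valid <- c(0, cumsum(is_valid))
  starts <- seq(0, len - 1, by = step)
  ends <- pmin(starts + window_size, len)
  gc_n <- cum_gc[ends + 1] - cum_gc[starts + 1]
  valid_n <- cum_valid[ends + 1] - cum_valid[starts + 1]
  tibble(scaffold = scaffold, start = starts, end = ends,
         gc = ifelse(valid_n > 0, gc_n / valid_n, NA_real_),
         n_valid = valid_n)
}

as_sequence_string <- function(sequence) {
  if (inherits(sequence, "DNAStringSet") || inherits(sequence, "XStringSet")) {
    stopifnot(length(sequence) == 1)
    return(as.character(sequence[[1]]))
  }
  if (inherits(sequence, "XString")) return(as.character(sequence))
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence
}

#' Sliding-window GC for every scaffold of a genome
#'
#' @param sequences A named [Biostrings::DNAStringSet] (or named character
#'   vector), e.g. `genome$sequences`.
#' @inheritParams gc_sliding
#' @return Row-bound [gc_sliding()] tibbles, one block per scaffold.
#' @export
gc_sliding_genome <- function(sequences, window_size = 1e5, step = 1e3) {
  nms <- names(sequences)
  stopifnot(!is.null(nms))
  purrr::map_dfr(nms, function(nm) {
    gc_sliding(sequences[nm], window_size, step, scaffold = nm)
  })
}

#' Per-window feature counts (gene or repeat density)
#'
#' Counts each feature in exactly one window — the window containing its
#' anchor position (the feature start by default, its midpoint on request) —
#' so the track total always equals the number of input features.
#'
#' @param features A tibble of intervals with columns `scaffold`, `start`,
#'   `end` (0-based half-open).
#' @param grid Window grid from [make_windows()].
#' @param anchor `"start"` or `"midpoint"`.
#' @return The grid tibble plus an integer `count` column.
#' @export
feature_density <- function(features, grid, anchor = c("start", "midpoint")) {
  anchor <- match.arg(anchor)
  stopifnot(is.data.frame(features),
            all(c("scaffold", "start", "end") %in% names(features)))
  unknown <- setdiff(unique(features$scaffold), unique(grid$scaffold))
  if (length(unknown) > 0) {
    abort(paste0("features on scaffold(s) absent from the grid: ",
                 paste(unknown, collapse = ", ")))
  }
  out <- as_tibble(grid)
  out$count <- 0L
  if (nrow(features) > 0) {
    pos <- if (anchor == "start") features$start
           else floor((features$start + features$end) / 2)
    ws <- grid_window_size(grid)
    key_f <- paste(features$scaffold, pmin(
      floor(pos / ws),
      tapply_last_window(features$scaffold, grid)))
    key_w <- paste(grid$scaffold, grid$window)
    tab <- table(key_f)
    idx <- match(names(tab), key_w)
    if (anyNA(idx)) abort("feature anchor outside the window grid")
    out$count[idx] <- as.integer(tab)
  }
  attr(out, "window_size") <- attr(grid, "window_size")
  out
}

# highest window index available per scaffold, aligned to a feature vector
tapply_last_window <- function(scaffold, grid) {
  last <- tapply(grid$window, grid$scaffold, max)
  as.numeric(last[scaffold])
}

#' N50 of a set of scaffold lengths
#'
#' The smallest length `L` such that scaffolds of length >= `L` together
#' cover at least half the assembly.
#'
#' @param lengths Numeric vector of scaffold lengths (all > 0).
#' @return A single length in bp.
#' @examples
#' n50(c(5, 4, 3, 2, 1)) # 4
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) abort("n50: empty length list")
  if (any(lengths <= 0)) abort("n50: lengths must be positive")
  lens <- sort(lengths, decreasing = TRUE)
  csum <- cumsum(lens)
  lens[which(csum >= sum(lens) / 2)[1]]
}

#' Assembly summary statistics
#'
#' @param sequences A named [Biostrings::DNAStringSet], a `genome_model`, or
#'   a numeric vector of lengths (in which case `global_gc` is `NA`).
#' @return A one-row tibble: `n_scaffolds`, `total_length`, `n50`, `largest`,
#'   `global_gc` (fraction over unambiguous bases).
#' @export
assembly_stats <- function(sequences) {
  if (inherits(sequences, "genome_model")) {
    sequences <- sequences$sequences %||%
      setNames(sequences$scaffolds$length, sequences$scaffolds$name)
  }
  if (is.numeric(sequences)) {
    lens <- as.numeric(sequences)
    gc <- NA_real_
  } else {
    if (is.character(sequences)) {
      sequences <- Biostrings::DNAStringSet(sequences)
    }
    lens <- Biostrings::width(sequences)
    freq <- Biostrings::alphabetFrequency(sequences)
    acgt <- colSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
    gc <- sum(acgt[c("C", "G")]) / sum(acgt)
  }
  tibble(n_scaffolds = length(lens), total_length = sum(lens),
         n50 = n50(lens), largest = max(lens), global_gc = gc)
}

#' Completeness percentage from found/total ortholog-group counts
#'
#' The usual benchmark-completeness arithmetic: the percentage of expected
#' single-copy ortholog groups recovered in an assembly, reported both at
#' full precision and rounded to the nearest integer percent as such figures
#' are usually printed.
#'
#' @param found Number of groups found (0 <= `found` <= `total`).
#' @param total Number of groups assessed (> 0).
#' @return A one-row tibble: `found`, `total`, `percent` (full precision),
#'   `percent_rounded`.
#' @examples
#' completeness_percent(854, 982)
#' @export
completeness_percent <- function(found, total) {
  if (!is.numeric(total) || total <= 0) abort("total must be > 0")
  if (found < 0 || found > total) abort("found must be in [0, total]")
  pct <- 100 * found / total
  tibble(found = found, total = total, percent = pct,
         percent_rounded = round(pct))
}

#' Detect tandem gene clusters by a gap sweep
#'
#' Sweeps each scaffold's genes left to right (sorted by start) and joins a
#' gene to the open cluster when its start lies within `max_gap` of the
#' rightmost gene end seen so far in that cluster (overlapping genes have gap
#' 0 and always join). Measuring the gap from the rightmost end seen — not
#' merely the previous gene's end — makes the sweep exactly equivalent to
#' transitive closure under the pairwise gap relation, including when a long
#' gene fully contains later ones. Clusters with fewer than `min_size`
#' members are discarded.
#'
#' @param genes A tibble with columns `scaffold`, `start`, `end`, and
#'   optionally `gene_id` (0-based half-open intervals).
#' @param max_gap Maximum inter-gene gap in bp (default 10,000).
#' @param min_size Minimum cluster size (default 3, >= 2).
#' @return A tibble of clusters: `scaffold`, `start`, `end`, `n_genes`,
#'   `gene_ids` (comma-joined member ids).
#' @export
find_clusters <- function(genes, max_gap = 1e4, min_size = 3) {
  stopifnot(max_gap >= 0, min_size >= 2)
  stopifnot(all(c("scaffold", "start", "end") %in% names(genes)))
  genes <- as_tibble(genes)
  if (!"gene_id" %in% names(genes)) {
    genes$gene_id <- sprintf("g%05d", seq_len(nrow(genes)))
  }
  genes <- arrange(genes, .data$scaffold, .data$start, .data$end)
  out <- genes |>
    group_by(.data$scaffold) |>
    group_modify(function(df, key) sweep_clusters(df, max_gap)) |>
    ungroup() |>
    filter(.data$n_genes >= min_size)
  attr(out, "max_gap") <- max_gap
  attr(out, "min_size") <- min_size
  out
}

sweep_clusters <- function(df, max_gap) {
  # running max end; new cluster when start - max_end_so_far > max_gap
  run_max <- cummax(df$end)
  gap <- df$start - dplyr::lag(run_max, default = -Inf)
  cl <- cumsum(gap > max_gap)
  df |>
    mutate(.cluster = cl) |>
    group_by(.data$.cluster) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_genes = n(),
              gene_ids = paste(.data$gene_id, collapse = ","),
              .groups = "drop") |>
    select("start", "end", "n_genes", "gene_ids")
}
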