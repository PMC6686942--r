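#' Load a one-to-one ortholog table from TSV
#'
#' Expects a five-column tab-separated table with header
#' `focal_gene  focal_scaffold  focal_start  ref_gene  ref_chromosome`
#' (positions in bp, 0-based gene starts). Enforces the one-to-one contract —
#' a duplicated focal or reference gene id is an error — and, when scaffold
#' lengths are supplied, rejects out-of-bounds positions.
#'
#' @param path Path to the TSV (lines starting `#` ignored).
#' @param scaffold_lengths Optional named lengths / data frame /
#'   `genome_model` for bounds checking.
#' @return A tibble of ortholog pairs (same columns as
#'   [simulate_orthologs()]).
#' @export
load_orthologs <- function(path, scaffold_lengths = NULL) {
  cols <- c("focal_gene", "focal_scaffold", "focal_start", "ref_gene",
            "ref_chromosome")
  tab <- tryCatch(
    suppressWarnings(
      readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    col_types = readr::cols(
                      focal_gene = readr::col_character(),
                      focal_scaffold = readr::col_character(),
                      focal_start = readr::col_double(),
                      ref_gene = readr::col_character(),
                      ref_chromosome = readr::col_character()))),
    error = function(e) abort(paste0("cannot parse ortholog TSV: ",
                                     conditionMessage(e))))
  missing_cols <- setdiff(cols, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("ortholog TSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tab <- tab[cols]
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    abort(paste0("malformed ortholog TSV at line(s) ",
                 paste(unique(prob$row), collapse = ", ")))
  }
  if (anyNA(tab$focal_start)) {
    abort(paste0("malformed ortholog TSV: non-numeric focal_start at row(s) ",
                 paste(which(is.na(tab$focal_start)), collapse = ", ")))
  }
  validate_orthologs(tab, scaffold_lengths)
  tab
}

validate_orthologs <- function(tab, scaffold_lengths = NULL) {
  dup_f <- tab$focal_gene[duplicated(tab$focal_gene)]
  dup_r <- tab$ref_gene[duplicated(tab$ref_gene)]
  if (length(dup_f) > 0 || length(dup_r) > 0) {
    abort(paste0("ortholog table is not one-to-one; duplicated id(s): ",
                 paste(unique(c(dup_f, dup_r)), collapse = ", ")))
  }
  if (!is.null(scaffold_lengths)) {
    lens <- as_scaffold_lengths(scaffold_lengths)
    unknown <- setdiff(unique(tab$focal_scaffold), names(lens))
    if (length(unknown) > 0) {
      abort(paste0("ortholog scaffold(s) not in genome: ",
                   paste(unknown, collapse = ", ")))
    }
    bad <- tab$focal_start < 0 |
      tab$focal_start >= lens[tab$focal_scaffold]
    if (any(bad)) {
      abort(paste0("ortholog position(s) outside scaffold bounds for: ",
                   paste(tab$focal_gene[bad], collapse = ", ")))
    }
  }
  invisible(tab)
}

#' Paint windows by reference-chromosome ortholog fractions
#'
#' Assigns each ortholog pair to the window containing its focal gene start
#' and, per window, tallies pairs by reference chromosome. Each window
#' reports the fraction of its orthologs attributed to every reference
#' chromosome (fractions sum to 1); windows containing zero orthologs are
#' flagged `no_synteny` — the painting's "no synteny" state — rather than
#' given fractions.
#'
#' @param orthologs Ortholog-pair tibble ([load_orthologs()] /
#'   [simulate_orthologs()]).
#' @param grid Window grid from [make_windows()] (500-kb windows are the
#'   usual macrosynteny scale).
#' @param ref_chromosomes Optional ordered character vector of reference
#'   chromosome labels; defaults to the sorted labels present. The order is
#'   the documented tie-break order for dominance.
#' @return A `painting_matrix` object: `windows` (grid plus `total`,
#'   `no_synteny`), `fractions` (long tibble `scaffold`, `start`, `end`,
#'   `ref_chromosome`, `count`, `fraction`), `ref_chromosomes`; supports
#'   [tidy()] and [autoplot()].
#' @export
paint <- function(orthologs, grid, ref_chromosomes = NULL) {
  stopifnot(is.data.frame(orthologs))
  validate_orthologs(orthologs)
  unknown <- setdiff(unique(orthologs$focal_scaffold), unique(grid$scaffold))
  if (length(unknown) > 0) {
    abort(paste0("orthologs on scaffold(s) absent from the grid: ",
                 paste(unknown, collapse = ", ")))
  }
  if (is.null(ref_chromosomes)) {
    ref_chromosomes <- sort(unique(orthologs$ref_chromosome))
  }
  ws <- grid_window_size(grid)
  windows <- as_tibble(grid)
  key_w <- paste(windows$scaffold, windows$window)
  widx <- pmin(floor(orthologs$focal_start / ws),
               tapply_last_window(orthologs$focal_scaffold, grid))
  key_o <- paste(orthologs$focal_scaffold, widx)
  bad <- !key_o %in% key_w
  if (any(bad)) abort("ortholog position outside the window grid")

  counts <- tibble(key = key_o,
                   ref_chromosome = orthologs$ref_chromosome) |>
    count(.data$key, .data$ref_chromosome, name = "count")
  totals <- counts |> group_by(.data$key) |>
    summarise(total = sum(.data$count), .groups = "drop")
  windows$total <- totals$total[match(key_w, totals$key)]
  windows$total[is.na(windows$total)] <- 0L
  windows$no_synteny <- windows$total == 0L

  idx <- match(counts$key, key_w)
  fractions <- tibble(scaffold = windows$scaffold[idx],
                      start = windows$start[idx],
                      end = windows$end[idx],
                      ref_chromosome = counts$ref_chromosome,
                      count = as.integer(counts$count)) |>
    mutate(fraction = .data$count / windows$total[idx]) |>
    arrange(.data$scaffold, .data$start,
            match(.data$ref_chromosome, ref_chromosomes))
  structure(list(windows = windows, fractions = fractions,
                 ref_chromosomes = ref_chromosomes,
                 window_size = ws),
            class = "painting_matrix")
}

#' @export
print.painting_matrix <- function(x, ...) {
  cat("<painting_matrix> ", nrow(x$windows), " windows of ",
      format(x$window_size, big.mark = ","), " bp on ",
      length(unique(x$windows$scaffold)), " scaffolds; reference: ",
      paste(x$ref_chromosomes, collapse = ", "), "; ",
      sum(x$windows$no_synteny), " no-synteny windows\n", sep = "")
  invisible(x)
}

# dominant reference label per window: argmax fraction among labels reaching
# min_window_fraction; ties broken by the declared ref_chromosomes order;
# "none" when no label qualifies or the window has no orthologs.
window_dominance <- function(pm, min_window_fraction = 0.5) {
  dom <- pm$fractions |>
    filter(.data$fraction >= min_window_fraction) |>
    mutate(.ord = match(.data$ref_chromosome, pm$ref_chromosomes)) |>
    group_by(.data$scaffold, .data$start, .data$end) |>
    arrange(desc(.data$fraction), .data$.ord, .by_group = TRUE) |>
    summarise(dominant = dplyr::first(.data$ref_chromosome),
              .groups = "drop")
  pm$windows |>
    left_join(dom, by = c("scaffold", "start", "end")) |>
    mutate(dominant = dplyr::coalesce(.data$dominant, "none")) |>
    select("scaffold", "start", "end", "window", "total", "no_synteny",
           "dominant")
}

#' Summarise per-scaffold homology and flag fusion signatures
#'
#' For each window the dominant reference chromosome is the label with the
#' largest ortholog fraction, provided that fraction reaches
#' `min_window_fraction` (ties broken by the painting's declared label
#' order). Dominant-window widths are accumulated into per-scaffold,
#' per-reference-chromosome spans; a scaffold whose spans attribute at least
#' `min_span_bp` to two or more reference chromosomes carries a fusion
#' signature (`fusion_flag`), the painting pattern left by an ancestral
#' chromosome fusion or translocation.
#'
#' @param pm A `painting_matrix` from [paint()].
#' @param min_span_bp Span threshold in bp for a chromosome to count towards
#'   the fusion flag (default 1 Mb).
#' @param min_window_fraction Minimum fraction for window dominance
#'   (default 0.5).
#' @return A `homology_report`: tibble with one row per scaffold —
#'   `scaffold`, `dominant_ref` (largest span; `"none"` if no window is
#'   dominated), `n_ref_over_threshold`, `fusion_flag` — carrying the long
#'   span table in `attr(, "spans")` and per-window dominance in
#'   `attr(, "window_dominance")`; supports [tidy()] and [glance()].
#' @export
summarize_homology <- function(pm, min_span_bp = 1e6,
                               min_window_fraction = 0.5) {
  stopifnot(inherits(pm, "painting_matrix"), min_span_bp >= 0)
  dom <- window_dominance(pm, min_window_fraction)
  spans <- dom |>
    filter(.data$dominant != "none") |>
    group_by(.data$scaffold, ref_chromosome = .data$dominant) |>
    summarise(span_bp = sum(.data$end - .data$start),
              n_windows = n(), .groups = "drop")
  per_scaffold <- purrr::map_dfr(unique(pm$windows$scaffold), function(sc) {
    sp <- spans |> filter(.data$scaffold == sc)
    if (nrow(sp) == 0) {
      return(tibble(scaffold = sc, dominant_ref = "none",
                    n_ref_over_threshold = 0L, fusion_flag = FALSE))
    }
    sp <- sp |>
      arrange(desc(.data$span_bp),
              match(.data$ref_chromosome, pm$ref_chromosomes))
    over <- sum(sp$span_bp >= min_span_bp)
    tibble(scaffold = sc, dominant_ref = sp$ref_chromosome[1],
           n_ref_over_threshold = as.integer(over),
           fusion_flag = over >= 2L)
  })
  structure(per_scaffold,
            spans = spans, window_dominance = dom,
            min_span_bp = min_span_bp,
            min_window_fraction = min_window_fraction,
            class = c("homology_report", class(per_scaffold)))
}

#' Locate dominant-label change points along scaffolds
#'
#' Scans each scaffold's windows in order and reports every boundary where
#' the dominant reference chromosome changes between two informative windows
#' (windows dominated by `"none"` are skipped, so sparse windows do not split
#' a span). For a fused scaffold the reported position estimates the fusion
#' breakpoint to window resolution.
#'
#' @param report A `homology_report` from [summarize_homology()].
#' @return A tibble: `scaffold`, `position` (bp, the boundary between the two
#'   windows), `from`, `to`.
#' @export
detect_breakpoints <- function(report) {
  dom <- attr(report, "window_dominance")
  stopifnot(!is.null(dom))
  dom |>
    filter(.data$dominant != "none") |>
    group_by(.data$scaffold) |>
    arrange(.data$start, .by_group = TRUE) |>
    group_modify(function(df, key) {
      if (nrow(df) < 2) {
        return(tibble(position = numeric(0), from = character(0),
                      to = character(0)))
      }
      chg <- which(df$dominant[-1] != df$dominant[-nrow(df)])
      tibble(position = df$end[chg], from = df$dominant[chg],
             to = df$dominant[chg + 1])
    }) |>
    ungroup()
}

#' @export
print.homology_report <- function(x, ...) {
  NextMethod()
  n_fus <- sum(x$fusion_flag)
  if (n_fus > 0) {
    cat("# fusion signature on: ",
        paste(x$scaffold[x$fusion_flag], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
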