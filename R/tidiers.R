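# broom-style accessors for the fitted-result objects

#' Tidy a sex-chromosome scan
#'
#' @param x A `sex_scan` from [scan_sex_chromosomes()].
#' @param ... Unused.
#' @return The per-scaffold call table (one row per scaffold).
#' @export
tidy.sex_scan <- function(x, ...) x$calls

#' One-row summary of a sex-chromosome scan
#'
#' @inheritParams tidy.sex_scan
#' @return A tibble: scaffold/window counts, calls per class, window size.
#' @export
glance.sex_scan <- function(x, ...) {
  tibble(n_scaffolds = nrow(x$calls),
         n_windows = nrow(x$ratio),
         n_masked = sum(x$ratio$masked),
         n_x_linked = sum(x$calls$call == "X-linked"),
         n_autosomal = sum(x$calls$call == "autosomal"),
         n_ambiguous = sum(x$calls$call == "ambiguous"),
         window_size = x$params$window_size)
}

#' Tidy a painting matrix
#'
#' @param x A `painting_matrix` from [paint()].
#' @param ... Unused.
#' @return A long tibble: one row per (window, reference chromosome) with
#'   `count` and `fraction`; no-synteny windows appear once with
#'   `ref_chromosome = "none"` and `NA` fraction.
#' @export
tidy.painting_matrix <- function(x, ...) {
  empty <- x$windows |>
    filter(.data$no_synteny) |>
    mutate(ref_chromosome = "none", count = 0L, fraction = NA_real_) |>
    select("scaffold", "start", "end", "ref_chromosome", "count", "fraction")
  bind_rows(x$fractions, empty) |>
    arrange(.data$scaffold, .data$start)
}

#' One-row summary of a painting matrix
#'
#' @inheritParams tidy.painting_matrix
#' @return A tibble: window/scaffold counts, ortholog total, no-synteny
#'   window count.
#' @export
glance.painting_matrix <- function(x, ...) {
  tibble(n_scaffolds = length(unique(x$windows$scaffold)),
         n_windows = nrow(x$windows),
         n_orthologs = sum(x$windows$total),
         n_no_synteny = sum(x$windows$no_synteny),
         n_ref_chromosomes = length(x$ref_chromosomes),
         window_size = x$window_size)
}

#' Tidy a homology report
#'
#' @param x A `homology_report` from [summarize_homology()].
#' @param ... Unused.
#' @return The long span table: `scaffold`, `ref_chromosome`, `span_bp`,
#'   `n_windows`.
#' @export
tidy.homology_report <- function(x, ...) attr(x, "spans")

#' One-row summary of a homology report
#'
#' @inheritParams tidy.homology_report
#' @return A tibble with scaffold counts and the number of fusion-flagged
#'   scaffolds.
#' @export
glance.homology_report <- function(x, ...) {
  tibble(n_scaffolds = nrow(x),
         n_fusion_flagged = sum(x$fusion_flag),
         min_span_bp = attr(x, "min_span_bp"),
         min_window_fraction = attr(x, "min_window_fraction"))
}
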