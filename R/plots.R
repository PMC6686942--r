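# ggplot2 views of the result objects. Scaffolds are shown longest to
# shortest, the conventional karyogram layout.

#' Plot a sex-chromosome scan
#'
#' Per-window log2(female/male) ratio along each scaffold, faceted by
#' scaffold from longest to shortest, with the X and autosome call bands
#' shaded. X-linked scaffolds sit on the log2 = 1 line, autosomes on 0.
#'
#' @param object A `sex_scan`.
#' @param min_length Display filter: only scaffolds at least this long are
#'   drawn (a plotting option only; calls are made for every scaffold).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sex_scan <- function(object, min_length = 0, ...) {
  keep <- object$calls$scaffold[object$calls$length >= min_length]
  dat <- object$ratio |>
    filter(!.data$masked, .data$scaffold %in% keep) |>
    mutate(scaffold = factor(.data$scaffold, levels = keep))
  bands <- tibble(
    lo = c(object$params$x_band[1], object$params$autosome_band[1]),
    hi = c(object$params$x_band[2], object$params$autosome_band[2]),
    band = c("X-linked", "autosomal"))
  ggplot2::ggplot(dat, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                    y = .data$log2_ratio)) +
    ggplot2::geom_rect(data = bands, inherit.aes = FALSE,
                       ggplot2::aes(xmin = -Inf, xmax = Inf, ymin = .data$lo,
                                    ymax = .data$hi, fill = .data$band),
                       alpha = 0.15) +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dotted",
                        linewidth = 0.3) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::facet_wrap(~scaffold, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c("X-linked" = "orange",
                                          "autosomal" = "steelblue")) +
    ggplot2::labs(x = "position (Mb)", y = "log2(female / male) depth",
                  fill = "call band") +
    ggplot2::theme_minimal()
}

#' Plot a painting matrix as a chromosome-paint heat grid
#'
#' One row per focal scaffold (longest to shortest), one tile per window,
#' filled by the dominant reference chromosome and shaded by its ortholog
#' fraction; windows with no orthologs are drawn in red as "no synteny".
#'
#' @param object A `painting_matrix`.
#' @param min_window_fraction Dominance threshold passed to the per-window
#'   labelling (see [summarize_homology()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.painting_matrix <- function(object, min_window_fraction = 0.5,
                                     ...) {
  dom <- window_dominance(object, min_window_fraction)
  lens <- dom |> group_by(.data$scaffold) |>
    summarise(len = max(.data$end), .groups = "drop") |>
    arrange(desc(.data$len))
  dom <- dom |>
    mutate(scaffold = factor(.data$scaffold, levels = rev(lens$scaffold)),
           state = ifelse(.data$no_synteny, "no synteny", .data$dominant))
  pal <- grDevices::hcl.colors(max(3, length(object$ref_chromosomes)),
                               "Dark 3")[seq_along(object$ref_chromosomes)]
  cols <- c(setNames(pal, object$ref_chromosomes),
            "none" = "grey80", "no synteny" = "red")
  ggplot2::ggplot(dom, ggplot2::aes(xmin = .data$start / 1e6,
                                    xmax = .data$end / 1e6,
                                    ymin = as.integer(.data$scaffold) - 0.4,
                                    ymax = as.integer(.data$scaffold) + 0.4,
                                    fill = .data$state)) +
    ggplot2::geom_rect(colour = "white", linewidth = 0.1) +
    ggplot2::scale_y_continuous(breaks = seq_len(nlevels(dom$scaffold)),
                                labels = levels(dom$scaffold)) +
    ggplot2::scale_fill_manual(values = cols) +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  fill = "reference\nchromosome") +
    ggplot2::theme_minimal()
}

#' Plot a windowed landscape track
#'
#' Generic per-scaffold line plot for GC, gene-density or repeat-density
#' tracks.
#'
#' @param track A track tibble with `scaffold`, `start`, `end` and a value
#'   column.
#' @param value Name of the value column (e.g. `"gc"`, `"count"`).
#' @return A ggplot object.
#' @export
plot_track <- function(track, value) {
  stopifnot(value %in% names(track))
  ggplot2::ggplot(track,
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data[[value]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~scaffold, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = value) +
    ggplot2::theme_minimal()
}
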