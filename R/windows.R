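#' Tile scaffolds into fixed windows
#'
#' Builds the non-overlapping window grid used by all windowed statistics:
#' each scaffold is cut into `ceiling(length / window_size)` contiguous
#' windows in 0-based half-open coordinates, the last of which may be shorter.
#' The concatenation of a scaffold's windows exactly tiles it.
#'
#' @param scaffold_lengths A named numeric vector (`name -> length`) or a data
#'   frame with columns `name`/`scaffold` and `length`.
#' @param window_size Window size in bp (default 100,000, the standard
#'   coverage/density window).
#' @return A tibble with columns `scaffold`, `start`, `end`, `window`
#'   (0-based index within scaffold), carrying `window_size` as an attribute.
#' @examples
#' make_windows(c(s1 = 250000), 100000)
#' @export
make_windows <- function(scaffold_lengths, window_size = 1e5) {
  lens <- as_scaffold_lengths(scaffold_lengths)
  if (!is.numeric(window_size) || length(window_size) != 1 ||
      window_size < 1) {
    abort("window_size must be a single integer >= 1")
  }
  if (any(lens < 1)) {
    abort(paste0("non-positive scaffold length for: ",
                 paste(names(lens)[lens < 1], collapse = ", ")))
  }
  grid <- purrr::map_dfr(names(lens), function(nm) {
    len <- lens[[nm]]
    starts <- seq(0, len - 1, by = window_size)
    tibble(scaffold = nm, start = starts,
           end = pmin(starts + window_size, len),
           window = seq_along(starts) - 1L)
  })
  attr(grid, "window_size") <- window_size
  attr(grid, "scaffold_lengths") <- lens
  grid
}

as_scaffold_lengths <- function(x) {
  if (inherits(x, "genome_model")) {
    return(setNames(x$scaffolds$length, x$scaffolds$name))
  }
  if (is.data.frame(x)) {
    nm_col <- intersect(c("name", "scaffold"), names(x))[1]
    if (is.na(nm_col) || !"length" %in% names(x)) {
      abort("scaffold lengths data frame needs columns name/scaffold and length")
    }
    return(setNames(x$length, x[[nm_col]]))
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  abort("scaffold_lengths must be a named numeric vector, a data frame, or a genome_model")
}

grid_window_size <- function(grid) {
  ws <- attr(grid, "window_size")
  if (is.null(ws)) ws <- max(grid$end - grid$start)
  ws
}
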