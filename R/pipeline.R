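# Pipeline configuration ------------------------------------------------

pipeline_defaults <- function() {
  list(
    simulate = TRUE,
    genome = NULL, female = NULL, male = NULL,
    genes = NULL, repeats = NULL, orthologs = NULL,
    out_dir = "karyoscope_out",
    seed = 1L,
    coverage_window = 1e5, gc_window = 1e5, gc_step = 1e3,
    density_window = 1e5, paint_window = 5e5,
    min_mapq = 0, min_depth = 0,
    x_band_low = 0.6, x_band_high = 1.4,
    autosome_band_low = -0.4, autosome_band_high = 0.4,
    min_unmasked_fraction = 0.5,
    cluster_max_gap = 1e4, cluster_min_size = 3,
    min_span_bp = 1e6, min_window_fraction = 0.5,
    depth = 20, read_length = 100,
    ortholog_density = 20, ortholog_dropout = 0.5
  )
}

config_path_keys <- c("genome", "female", "male", "genes", "repeats",
                      "orthologs", "out_dir")

#' Validate a pipeline configuration
#'
#' Reads a flat YAML key-value file (or takes a named list), fills defaults
#' for absent keys, and rejects unknown keys — suggesting the nearest known
#' key — and type/range violations, reporting all problems at once.
#'
#' @param config Path to a YAML file, or a named list of overrides; an empty
#'   file or `NULL` yields the full default configuration.
#' @return The validated configuration list.
#' @examples
#' cfg <- validate_config(list(depth = 30))
#' cfg$depth
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  problems <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  for (key in unknown) {
    dist <- utils::adist(key, names(defaults))
    hint <- names(defaults)[which.min(dist)]
    problems <- c(problems,
                  paste0("unknown key '", key, "' (did you mean '", hint,
                         "'?)"))
  }
  cfg <- utils::modifyList(defaults, config[setdiff(names(config), unknown)])
  num_keys <- setdiff(names(defaults),
                      c(config_path_keys, "simulate", "seed"))
  for (key in num_keys) {
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1) {
      problems <- c(problems, paste0("'", key, "' must be a single number"))
    }
  }
  for (key in c("coverage_window", "gc_window", "gc_step", "density_window",
                "paint_window")) {
    if (is.numeric(cfg[[key]]) && length(cfg[[key]]) == 1 &&
        cfg[[key]] < 1) {
      problems <- c(problems, paste0("'", key, "' must be >= 1"))
    }
  }
  for (key in config_path_keys) {
    if (!is.null(cfg[[key]]) && !is.character(cfg[[key]])) {
      problems <- c(problems, paste0("'", key, "' must be a path"))
    }
  }
  if (!is.logical(cfg$simulate) || length(cfg$simulate) != 1) {
    problems <- c(problems, "'simulate' must be true or false")
  }
  if (length(problems) > 0) {
    abort(paste0("invalid configuration:\n",
                 paste0("  - ", problems, collapse = "\n")))
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# Pipeline ---------------------------------------------------------------

#' Run the full karyotyping pipeline
#'
#' Orchestrates simulate (optional) -> sex scan -> landscape -> synteny
#' painting as one seeded run, writing every stage's tables under
#' `config$out_dir` with `#` headers carrying the tool version, a
#' configuration hash and the seed, plus a combined per-scaffold report.
#' Reruns with identical configuration and inputs are byte-identical.
#'
#' @param config A configuration list or YAML path (see [validate_config()]).
#' @param quiet Suppress progress logging to stderr (the `run.log` file is
#'   always written).
#' @return A `karyoscope_run` list: `report` (per-scaffold tibble), `scan`
#'   (`sex_scan`), `painting`, `homology`, `stats`, `clusters`, `files`
#'   (named vector of outputs), `config`.
#' @export
run_pipeline <- function(config = NULL, quiet = FALSE) {
  cfg <- validate_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(paste0("cannot create output directory: ", out_dir))
  }
  log_file <- file.path(out_dir, "run.log")
  cat("", file = log_file)
  log_line <- function(stage, msg) {
    line <- paste0("[", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "] [",
                   stage, "] ", msg)
    cat(line, "\n", file = log_file, append = TRUE)
    if (!quiet) message(line)
  }
  hdr <- c(paste0("karyoscope ",
                  as.character(utils::packageVersion("karyoscope"))),
           paste0("seed=", cfg$seed),
           # hash the analysis-relevant configuration, not the output path
           paste0("config_hash=",
                  rlang::hash(cfg[setdiff(names(cfg), "out_dir")])))
  files <- character(0)
  emit <- function(df, name, writer = write_track_tsv) {
    path <- file.path(out_dir, name)
    partial <- paste0(path, ".partial")
    writer(df, partial)
    file.rename(partial, path)
    files[[name]] <<- path
    path
  }
  run_stage <- function(stage, expr) {
    log_line(stage, "start")
    res <- tryCatch(expr, error = function(e) {
      log_line(stage, paste0("FAILED: ", conditionMessage(e)))
      abort(paste0("pipeline stage '", stage, "' failed: ",
                   conditionMessage(e)))
    })
    log_line(stage, "done")
    res
  }

  # --- inputs ---
  inputs <- run_stage("inputs", {
    if (isTRUE(cfg$simulate)) {
      genome <- simulate_genome(seed = cfg$seed)
      reads_f <- simulate_reads(genome, "female", mean_depth = cfg$depth,
                                read_length = cfg$read_length,
                                seed = cfg$seed + 1L)
      reads_m <- simulate_reads(genome, "male", mean_depth = cfg$depth,
                                read_length = cfg$read_length,
                                seed = cfg$seed + 2L)
      orth <- simulate_orthologs(genome, n_per_mb = cfg$ortholog_density,
                                 dropout = cfg$ortholog_dropout,
                                 seed = cfg$seed + 3L)
      bundle <- write_fixture_bundle(genome, reads_f, reads_m, orth,
                                     file.path(out_dir, "simulated"))
      list(sequences = genome$sequences,
           lengths = setNames(genome$scaffolds$length,
                              genome$scaffolds$name),
           female = reads_f, male = reads_m,
           genes = genome$genes, repeats = genome$repeats,
           orthologs = orth, bundle = bundle)
    } else {
      need <- c("genome", "female", "male", "genes", "repeats", "orthologs")
      missing_keys <- need[vapply(need, function(k) is.null(cfg[[k]]),
                                  logical(1))]
      if (length(missing_keys) > 0) {
        abort(paste0("missing input path(s) without simulate: ",
                     paste(missing_keys, collapse = ", ")))
      }
      seqs <- read_genome_fasta(cfg$genome)
      list(sequences = seqs,
           lengths = setNames(Biostrings::width(seqs), names(seqs)),
           female = cfg$female, male = cfg$male,
           genes = read_genes_gff3(cfg$genes),
           repeats = read_bed(cfg$repeats),
           orthologs = load_orthologs(
             cfg$orthologs,
             setNames(Biostrings::width(seqs), names(seqs))),
           bundle = NULL)
    }
  })

  # --- sex scan ---
  scan <- run_stage("sexscan", {
    scan <- scan_sex_chromosomes(
      inputs$female, inputs$male, inputs$lengths,
      window_size = cfg$coverage_window, min_mapq = cfg$min_mapq,
      min_depth = cfg$min_depth,
      x_band = c(cfg$x_band_low, cfg$x_band_high),
      autosome_band = c(cfg$autosome_band_low, cfg$autosome_band_high),
      min_unmasked_fraction = cfg$min_unmasked_fraction)
    emit(scan$ratio |>
           select("scaffold", "start", "end", depth_f = "depth_raw_f",
                  depth_m = "depth_raw_m", "log2_ratio", "masked"),
         "ratio_windows.tsv",
         function(df, p) write_track_tsv(df, p, hdr))
    emit(scan$calls, "sex_calls.tsv",
         function(df, p) write_track_tsv(df, p, hdr))
    emit(scan$ratio |> filter(!.data$masked), "ratio.bedgraph",
         function(df, p) write_bedgraph(df, p, value = "log2_ratio"))
    scan
  })

  # --- landscape ---
  landscape <- run_stage("landscape", {
    grid <- make_windows(inputs$lengths, cfg$density_window)
    gene_d <- feature_density(inputs$genes, grid)
    rep_d <- feature_density(inputs$repeats, grid)
    gc <- gc_sliding_genome(inputs$sequences, cfg$gc_window, cfg$gc_step)
    stats <- assembly_stats(inputs$sequences)
    clusters <- find_clusters(inputs$genes, max_gap = cfg$cluster_max_gap,
                              min_size = cfg$cluster_min_size)
    emit(gene_d, "gene_density.tsv",
         function(df, p) write_track_tsv(df, p, hdr))
    emit(rep_d, "repeat_density.tsv",
         function(df, p) write_track_tsv(df, p, hdr))
    emit(gc, "gc_track.tsv", function(df, p) write_track_tsv(df, p, hdr))
    emit(stats, "assembly_stats.tsv",
         function(df, p) write_track_tsv(df, p, hdr))
    emit(clusters |> mutate(name = .data$gene_ids) |>
           select("scaffold", "start", "end", "name"),
         "clusters.bed", write_bed)
    list(gene_density = gene_d, repeat_density = rep_d, gc = gc,
         stats = stats, clusters = clusters)
  })

  # --- painting ---
  paint_res <- run_stage("paint", {
    grid <- make_windows(inputs$lengths, cfg$paint_window)
    pm <- paint(inputs$orthologs, grid)
    hom <- summarize_homology(pm, min_span_bp = cfg$min_span_bp,
                              min_window_fraction = cfg$min_window_fraction)
    bps <- detect_breakpoints(hom)
    emit(painting_wide(pm), "painting.tsv",
         function(df, p) write_track_tsv(df, p, hdr))
    emit(as_tibble(hom), "homology.tsv",
         function(df, p) write_track_tsv(df, p, hdr))
    emit(bps, "breakpoints.tsv",
         function(df, p) write_track_tsv(df, p, hdr))
    list(pm = pm, homology = hom, breakpoints = bps)
  })

  # --- combined per-scaffold report ---
  report <- run_stage("report", {
    per_gc <- landscape$gc |>
      group_by(.data$scaffold) |>
      summarise(mean_gc = sum(.data$gc * .data$n_valid, na.rm = TRUE) /
                  sum(.data$n_valid[!is.na(.data$gc)]), .groups = "drop")
    rep <- scan$calls |>
      left_join(count(inputs$genes, .data$scaffold, name = "gene_count"),
                by = "scaffold") |>
      left_join(count(inputs$repeats, .data$scaffold,
                      name = "repeat_count"), by = "scaffold") |>
      left_join(per_gc, by = "scaffold") |>
      left_join(as_tibble(paint_res$homology)[
        c("scaffold", "dominant_ref", "fusion_flag")], by = "scaffold") |>
      mutate(gene_count = dplyr::coalesce(.data$gene_count, 0L),
             repeat_count = dplyr::coalesce(.data$repeat_count, 0L)) |>
      select("scaffold", "length", "call", "median_log2_ratio",
             "gene_count", "repeat_count", "mean_gc", "dominant_ref",
             "fusion_flag")
    emit(rep, "scaffold_report.tsv",
         function(df, p) write_track_tsv(df, p, hdr))
    rep
  })

  structure(list(report = report, scan = scan, painting = paint_res$pm,
                 homology = paint_res$homology,
                 breakpoints = paint_res$breakpoints,
                 stats = landscape$stats, clusters = landscape$clusters,
                 files = files, config = cfg),
            class = "karyoscope_run")
}

# wide painting table: one frac_<chrom> column per reference chromosome
painting_wide <- function(pm) {
  wide <- pm$fractions |>
    select("scaffold", "start", "end", "ref_chromosome", "fraction") |>
    mutate(ref_chromosome = paste0("frac_", .data$ref_chromosome)) |>
    tidyr::pivot_wider(names_from = "ref_chromosome",
                       values_from = "fraction", values_fill = 0)
  out <- pm$windows |>
    select("scaffold", window_start = "start", window_end = "end",
           "total", "no_synteny") |>
    left_join(wide, by = c("scaffold", "window_start" = "start",
                           "window_end" = "end"))
  frac_cols <- paste0("frac_", pm$ref_chromosomes)
  for (cc in frac_cols) {
    if (!cc %in% names(out)) out[[cc]] <- 0
    out[[cc]][is.na(out[[cc]])] <- 0
  }
  out[c("scaffold", "window_start", "window_end", "total", frac_cols,
        "no_synteny")]
}

#' @export
print.karyoscope_run <- function(x, ...) {
  cat("<karyoscope_run> seed ", x$config$seed, ", outputs in ",
      x$config$out_dir, "\n", sep = "")
  print(x$report, ...)
  invisible(x)
}
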