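# Readers lean on Biostrings / Rsamtools / rtracklayer; writers are plain
# text so headers and column layouts stay under package control. All tibble
# interval columns are 0-based half-open; GFF3 and SAM files are 1-based on
# disk per their standards, BED/BEDGRAPH 0-based half-open.

#' Read a genome FASTA
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write a genome FASTA (60-column wrapped)
#' @param sequences Named DNAStringSet or character vector.
#' @param path Output file.
#' @export
write_genome_fasta <- function(sequences, path) {
  if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  Biostrings::writeXStringSet(sequences, path, width = 60)
  invisible(path)
}

#' Read gene intervals from GFF3
#'
#' Imports `gene`-type features (all features if none are typed `gene`) and
#' converts to 0-based half-open coordinates.
#'
#' @param path GFF3 file.
#' @return A tibble: `scaffold`, `start`, `end`, `strand`, `gene_id`,
#'   `family` (from the `family` attribute when present).
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(S4Vectors::mcols(gr)$type == "gene")) {
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  }
  mc <- S4Vectors::mcols(gr)
  tibble(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(mc$ID),
    family = if ("family" %in% names(mc)) as.character(mc$family)
             else "none"
  )
}

#' Write gene intervals as GFF3
#' @param genes Gene tibble (`scaffold`, `start`, `end`, `strand`,
#'   `gene_id`, optional `family`; 0-based half-open).
#' @param path Output file.
#' @param source Value for the GFF3 source column.
#' @export
write_genes_gff3 <- function(genes, path, source = "karyoscope") {
  attrs <- paste0("ID=", genes$gene_id)
  if ("family" %in% names(genes)) {
    attrs <- paste0(attrs, ";family=", genes$family)
  }
  lines <- c("##gff-version 3",
             paste(genes$scaffold, source, "gene",
                   format(genes$start + 1, scientific = FALSE, trim = TRUE),
                   format(genes$end, scientific = FALSE, trim = TRUE),
                   ".", genes$strand, ".", attrs, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read BED3 intervals
#' @param path BED file (0-based half-open).
#' @return A tibble: `scaffold`, `start`, `end` (plus `name` if present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- tibble(scaffold = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1,
                end = as.numeric(GenomicRanges::end(gr)))
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm) && !all(is.na(nm))) out$name <- as.character(nm)
  out
}

#' Write intervals as BED (3 columns, plus a name column when given)
#' @param intervals Tibble with `scaffold`, `start`, `end`, optional `name`.
#' @param path Output file.
#' @export
write_bed <- function(intervals, path) {
  fields <- list(intervals$scaffold,
                 format(intervals$start, scientific = FALSE, trim = TRUE),
                 format(intervals$end, scientific = FALSE, trim = TRUE))
  if ("name" %in% names(intervals)) fields <- c(fields, list(intervals$name))
  writeLines(do.call(paste, c(fields, sep = "\t")), path)
  invisible(path)
}

#' Read a BEDGRAPH depth track
#' @param path BEDGRAPH file (`track`/comment lines skipped).
#' @return A tibble: `scaffold`, `start`, `end`, `depth`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(scaffold = character(0), start = numeric(0),
                  end = numeric(0), depth = numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 4)) abort("malformed BEDGRAPH: expected 4 columns")
  tibble(scaffold = vapply(parts, `[[`, "", 1),
         start = as.numeric(vapply(parts, `[[`, "", 2)),
         end = as.numeric(vapply(parts, `[[`, "", 3)),
         depth = as.numeric(vapply(parts, `[[`, "", 4)))
}

#' Write a per-window value track as BEDGRAPH
#' @param track Tibble with `scaffold`, `start`, `end` and a value column.
#' @param path Output file.
#' @param value Name of the value column (default `"depth"`).
#' @export
write_bedgraph <- function(track, path, value = "depth") {
  v <- track[[value]]
  writeLines(paste(track$scaffold,
                   format(track$start, scientific = FALSE, trim = TRUE),
                   format(track$end, scientific = FALSE, trim = TRUE),
                   sprintf("%.17g", v), sep = "\t"), path)
  invisible(path)
}

#' Write read placements as a minimal SAM file
#'
#' Emits an `@HD`/`@SQ` header and one mapped single-end record per
#' placement (1-based POS, `<len>M` CIGAR, no stored sequence), sufficient
#' for any SAM-consuming coverage tool.
#'
#' @param reads A `read_placements` object or placements tibble.
#' @param scaffold_lengths Named lengths / data frame / `genome_model` for
#'   the `@SQ` header.
#' @param path Output file.
#' @param mapq MAPQ written on every record.
#' @export
write_sam <- function(reads, scaffold_lengths, path, mapq = 60) {
  if (inherits(reads, "read_placements")) reads <- reads$placements
  lens <- as_scaffold_lengths(scaffold_lengths)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", names(lens), "\tLN:",
                     format(lens, scientific = FALSE, trim = TRUE)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(reads) > 0) {
    recs <- paste(sprintf("r%07d", seq_len(nrow(reads))), 0L,
                  reads$scaffold,
                  format(reads$start + 1, scientific = FALSE, trim = TRUE),
                  mapq, paste0(reads$read_length, "M"),
                  "*", 0L, 0L, "*", "*", sep = "\t")
    writeLines(recs, con)
  }
  invisible(path)
}

#' Write an ortholog table as TSV
#' @param orthologs Ortholog-pair tibble.
#' @param path Output file.
#' @export
write_orthologs_tsv <- function(orthologs, path) {
  readr::write_tsv(orthologs, path)
  invisible(path)
}

#' Write the complete synthetic fixture bundle
#'
#' Emits every input the downstream stages consume — genome FASTA, gene
#' GFF3, repeat BED, one SAM per sex, the ortholog TSV — plus a `truth.tsv`
#' recording the planted X scaffold and fusion map, so parameter-recovery
#' checks can compare calls against ground truth. All files round-trip
#' through the package's own readers.
#'
#' @param genome A `genome_model` with sequences.
#' @param reads_female,reads_male `read_placements` objects for the two
#'   sexes.
#' @param orthologs Ortholog-pair tibble.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the files written.
#' @export
write_fixture_bundle <- function(genome, reads_female, reads_male,
                                 orthologs, out_dir) {
  stopifnot(inherits(genome, "genome_model"))
  if (is.null(genome$sequences)) {
    abort("genome has no sequences; rerun simulate_genome(sequences = TRUE)")
  }
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    abort(paste0("cannot create output directory: ", out_dir))
  }
  paths <- c(
    genome = file.path(out_dir, "genome.fasta"),
    genes = file.path(out_dir, "genes.gff3"),
    repeats = file.path(out_dir, "repeats.bed"),
    female = file.path(out_dir, "female.sam"),
    male = file.path(out_dir, "male.sam"),
    orthologs = file.path(out_dir, "orthologs.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_genome_fasta(genome$sequences, paths[["genome"]])
  write_genes_gff3(genome$genes, paths[["genes"]])
  write_bed(genome$repeats, paths[["repeats"]])
  write_sam(reads_female, genome, paths[["female"]])
  write_sam(reads_male, genome, paths[["male"]])
  write_orthologs_tsv(orthologs, paths[["orthologs"]])
  truth <- bind_rows(
    tibble(record = "x_scaffold", scaffold = genome$truth_x,
           start = NA_real_, end = NA_real_, ref_chromosome = NA_character_),
    tibble(record = "fusion", scaffold = genome$fusion_map$focal_scaffold,
           start = genome$fusion_map$start, end = genome$fusion_map$end,
           ref_chromosome = genome$fusion_map$ref_chromosome))
  readr::write_tsv(truth, paths[["truth"]])
  paths
}

#' Read a fixture truth table
#' @param path `truth.tsv` written by [write_fixture_bundle()].
#' @return A list: `truth_x` (character vector), `fusion_map` (tibble).
#' @export
read_truth_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  list(
    truth_x = tab$scaffold[tab$record == "x_scaffold"],
    fusion_map = tab |>
      filter(.data$record == "fusion") |>
      select(focal_scaffold = "scaffold", "start", "end", "ref_chromosome")
  )
}

# "#"-headered TSV writer shared by the pipeline stage outputs
write_track_tsv <- function(df, path, header_lines = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header_lines) > 0) writeLines(paste0("# ", header_lines), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    body <- do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col)) format(col, scientific = FALSE, trim = TRUE,
                                  digits = 15)
      else as.character(col)
    }), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}
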