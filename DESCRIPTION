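Package: karyoscope
Title: Sex-Chromosome Identification, Genome Landscapes and Macrosynteny
    Painting for Nematode Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for karyotype-level analysis of chromosome-scale genome
    assemblies: identification of X-linked scaffolds from the female:male
    sequencing-depth ratio in fixed windows, windowed genome-landscape
    statistics (sliding-window GC content, gene and repeat density, N50 and
    other assembly summaries, tandem gene-cluster detection), and macrosynteny
    "chromosome painting" of scaffolds against a reference karyotype from
    one-to-one ortholog tables, including detection of chromosome-fusion
    signatures. A seeded synthetic-data generator produces toy genomes,
    annotations, sex-specific read placements and ortholog tables with the
    statistical structure the analyses assume, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    yaml,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
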