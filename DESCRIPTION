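Package: guidearray
Title: Design, Simulation and Nanopore QC of Golden Gate Guide RNA Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building ordered arrays of CRISPR guide RNA (gRNA)
    expression units by Golden Gate assembly of polymerase-cycling-assembly
    (PCA) products. Designs the single-stranded spacer oligos, position-specific
    primer pairs and type IIS junction overhangs for arrays of up to 20 units
    (optionally pooled spacers per position for array libraries); simulates
    assembled molecules and nanopore-style plasmid reads with controllable
    truncation, mutation and read-error rates; implements a sequencing QC
    pipeline (flank-based insert extraction, length binning into unit counts,
    alignment-based mutation profiling with region classification, and fuzzy
    spacer-to-pool mapping); and provides the clone-picking probability chain
    and library-diversity arithmetic used to plan screening effort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
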