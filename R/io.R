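# Readers and writers for the standard formats around the design/QC workflow.

#' Read spacers from FASTA or CSV
#'
#' CSV input needs columns `name` and `sequence` (optionally `position` and
#' `weight` for pooled-library designs). FASTA records are taken in file
#' order, one per position.
#'
#' @param path Input file; format inferred from the extension
#'   (`.fa`/`.fasta` vs `.csv`).
#' @return A tibble with columns `position`, `name`, `spacer`, `weight`,
#'   suitable for [build_array_design()].
#' @export
read_spacers <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("spacer file not found: %s", path),
          class = "guidearray_missing_input_error")
  }
  if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) {
    seqs <- Biostrings::readDNAStringSet(path)
    tibble(position = seq_along(seqs),
           name = sub("\\s.*$", "", names(seqs)),
           spacer = unname(as.character(seqs)),
           weight = 1)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
    if (!all(c("name", "sequence") %in% names(df))) {
      abort("spacer CSV needs columns 'name' and 'sequence'",
            class = "guidearray_validation_error")
    }
    tibble(position = if ("position" %in% names(df)) as.integer(df$position)
                      else seq_len(nrow(df)),
           name = as.character(df$name),
           spacer = toupper(as.character(df$sequence)),
           weight = if ("weight" %in% names(df)) as.numeric(df$weight) else 1)
  }
}

#' Read and write FASTQ
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] moving reads between files and the tidy
#' read tibbles the rest of the package uses.
#'
#' @param path FASTQ file.
#' @return `read_fastq()`: a tibble with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTQ not found: %s", path),
          class = "guidearray_missing_input_error")
  }
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = sub("\\s.*$", "", names(seqs)),
         sequence = as.character(seqs))
}

#' @rdname read_fastq
#' @param reads A tibble with `read_id` and `sequence`.
#' @param error_rate Per-base error rate used to pick the constant Phred
#'   quality written for every base.
#' @export
write_fastq <- function(reads, path, error_rate = 0) {
  q <- min(41L, as.integer(round(-10 * log10(max(error_rate, 1e-4)))))
  qchar <- rawToChar(as.raw(q + 33L))
  seqs <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  quals <- Biostrings::BStringSet(strrep(qchar, nchar(reads$sequence)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Write the oligo order sheet
#'
#' One row per single-stranded spacer oligo with a synthesis-scale hint
#' (standard desalted oligos suffice for this workflow).
#'
#' @param design An `array_design`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_order_sheet <- function(design, path) {
  stopifnot(inherits(design, "array_design"))
  sheet <- design$oligos |>
    mutate(oligo_name = sprintf("pos%02d_%s_spacer_oligo", .data$position,
                                .data$name),
           scale_hint = ifelse(.data$length <= 60, "25nm_desalted",
                               "100nm_desalted")) |>
    select("oligo_name", "position", "name", "sequence", "length",
           "scale_hint")
  readr::write_csv(sheet, path)
  invisible(path)
}

#' Write the position-primer CSV
#'
#' @inheritParams write_order_sheet
#' @export
write_primers_csv <- function(design, path) {
  stopifnot(inherits(design, "array_design"))
  pr <- design$primers |>
    tidyr::pivot_longer(c("fwd", "rev"), names_to = "direction",
                        values_to = "sequence") |>
    mutate(primer_name = sprintf("pos%02d_%s", .data$position,
                                 .data$direction)) |>
    select("primer_name", "position", "direction", "left_overhang",
           "right_overhang", "sequence")
  readr::write_csv(pr, path)
  invisible(path)
}

#' Write the design report JSON
#'
#' Serialises the design (overhangs, oligos, primers, expected sequences,
#' region maps, length table) to a single JSON report.
#'
#' @inheritParams write_order_sheet
#' @export
write_design_json <- function(design, path) {
  stopifnot(inherits(design, "array_design"))
  payload <- list(
    k = design$k,
    library_mode = design$library_mode,
    enzyme = design$fixtures$enzyme[c("name", "recognition", "cut_spacer",
                                      "overhang_len")],
    params = design$params,
    overhangs = as.character(design$overhang_set),
    oligos = design$oligos,
    primers = design$primers,
    unit_length_table = unname(design$unit_length_table),
    expected_insert = design$expected_insert,
    expected_plasmid = design$expected_plasmid,
    insert_regions = design$insert_regions
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# GenBank feature block helper: internal 0-based half-open coordinates become
# 1-based inclusive in GenBank
.gb_feature <- function(key, start0, end0, qualifiers) {
  loc <- sprintf("%d..%d", start0 + 1L, end0)
  c(sprintf("     %-16s%s", key, loc),
    vapply(names(qualifiers), function(q) {
      sprintf("                     /%s=\"%s\"", q, qualifiers[[q]])
    }, character(1)))
}

#' Write the expected plasmid as an annotated GenBank file
#'
#' Writes the circular expected plasmid with one annotated feature per unit
#' region (primer tails, U6 promoter, spacer, scaffold) plus the vector
#' flanks and each junction overhang.
#'
#' @inheritParams write_order_sheet
#' @export
write_genbank <- function(design, path) {
  stopifnot(inherits(design, "array_design"))
  seq <- design$expected_plasmid
  len <- nchar(seq)
  offset <- nchar(design$fixtures$vector_flank_up)  # insert start in plasmid
  lines <- c(
    sprintf("LOCUS       %-18s%d bp    DNA     circular SYN %s",
            "grna_array", len, format(Sys.Date(), "%d-%b-%Y")),
    "DEFINITION  Expected guide RNA array plasmid (designed sequence).",
    "FEATURES             Location/Qualifiers",
    .gb_feature("source", 0L, len, list(organism = "synthetic DNA construct",
                                        mol_type = "other DNA"))
  )
  lines <- c(lines,
             .gb_feature("misc_feature", 0L, offset,
                         list(label = "vector_flank_up")),
             .gb_feature("misc_feature", offset + nchar(design$expected_insert),
                         len, list(label = "vector_flank_down")))
  reg <- design$insert_regions
  for (i in seq_len(nrow(reg))) {
    lines <- c(lines, .gb_feature(
      "misc_feature", offset + reg$start[i], offset + reg$end[i],
      list(label = sprintf("unit%02d_%s", reg$unit[i], reg$region[i]))))
  }
  oh <- unclass(design$overhang_set)
  core_len <- nchar(design$units$pca_product[1]) -
    2L * .tail_len(design$fixtures$enzyme, design$params$pad)
  ohl <- design$fixtures$enzyme$overhang_len
  pos <- offset + c(0L, seq_len(design$k) * (core_len + ohl))
  for (j in seq_along(oh)) {
    lines <- c(lines, .gb_feature(
      "misc_feature", pos[j], pos[j] + ohl,
      list(label = sprintf("junction_overhang_%02d", j - 1L),
           note = oh[j])))
  }
  lines <- c(lines, "ORIGIN")
  low <- tolower(seq)
  for (s in seq(1L, len, by = 60L)) {
    chunk <- substr(low, s, min(s + 59L, len))
    blocks <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L),
                             nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", s, paste(blocks, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}
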