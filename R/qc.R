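# Nanopore QC pipeline: flank-based insert extraction, length binning into
# unit counts, alignment-based mutation profiling, spacer-to-pool mapping.

.as_read_tbl <- function(reads) {
  if (is.data.frame(reads)) {
    if (!all(c("read_id", "sequence") %in% names(reads))) {
      abort("reads data frame needs columns 'read_id' and 'sequence'",
            class = "guidearray_validation_error")
    }
    tibble(read_id = as.character(reads$read_id),
           sequence = toupper(as.character(reads$sequence)))
  } else {
    sq <- toupper(as.character(reads))
    ids <- names(reads) %||% sprintf("read_%05d", seq_along(sq))
    if (is.null(names(reads))) ids <- sprintf("read_%05d", seq_along(sq))
    tibble(read_id = ids, sequence = sq)
  }
}

#' Flanking sequences for insert extraction
#'
#' Returns the two backbone sequences immediately surrounding the insert
#' site, trimmed to `flank_len` nt, as used by [extract_inserts()].
#'
#' @param fixtures A `gg_fixtures` or `array_design` object.
#' @param flank_len Flank length in nt (default 30).
#' @return Named character vector with elements `up` and `down`.
#' @export
flanking_sequences <- function(fixtures, flank_len = 30L) {
  if (inherits(fixtures, "array_design")) fixtures <- fixtures$fixtures
  stopifnot(inherits(fixtures, "gg_fixtures"))
  fu <- fixtures$vector_flank_up
  fd <- fixtures$vector_flank_down
  c(up = substr(fu, nchar(fu) - flank_len + 1L, nchar(fu)),
    down = substr(fd, 1L, flank_len))
}

# best approximate occurrence of pattern in subject (both DNAString); returns
# NULL or list(start, end, edits) with 1-based inclusive coordinates
.best_flank_match <- function(subject, pattern, max_edits) {
  m <- Biostrings::matchPattern(pattern, subject, max.mismatch = max_edits,
                                with.indels = TRUE)
  if (length(m) == 0L) return(NULL)
  hits <- as.character(m)
  edits <- as.integer(adist(hits, as.character(pattern)))
  best <- which(edits == min(edits))[1]
  list(start = BiocGenerics::start(m)[best], end = BiocGenerics::end(m)[best],
       edits = edits[best])
}

#' Extract array inserts from whole-plasmid reads
#'
#' Searches each read, on both strands, for an approximate occurrence of the
#' upstream backbone flank followed by the downstream flank, and reports the
#' enclosed insert in design orientation. Reads lacking either flank (within
#' `max_error_rate` edits per flank, relative to flank length) are incomplete
#' plasmid reads and are discarded and counted.
#'
#' @param reads A tibble with `read_id` and `sequence` columns (e.g. from
#'   [read_fastq()] or [simulate_reads()]), or a character vector.
#' @param flank_up,flank_down Backbone sequences immediately 5' and 3' of the
#'   insert (at least 20 nt each); see [flanking_sequences()].
#' @param max_error_rate Maximum edit distance per flank match, as a fraction
#'   of the flank length.
#' @return An `insert_hits` tibble: `read_id`, `insert` (design orientation),
#'   `strand`, `up_flank_errors`, `down_flank_errors`, `insert_start`,
#'   `insert_end` (0-based half-open span in the original read). Attributes
#'   `n_reads` and `n_discarded` carry the discard accounting.
#' @export
extract_inserts <- function(reads, flank_up, flank_down, max_error_rate = 0.2) {
  if (nchar(flank_up) < 20L || nchar(flank_down) < 20L) {
    abort("flanking sequences must be at least 20 nt",
          class = "guidearray_validation_error")
  }
  reads <- .as_read_tbl(reads)
  up_pat <- Biostrings::DNAString(toupper(flank_up))
  dn_pat <- Biostrings::DNAString(toupper(flank_down))
  up_max <- floor(max_error_rate * nchar(flank_up))
  dn_max <- floor(max_error_rate * nchar(flank_down))

  hits <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    seq_fwd <- reads$sequence[i]
    len <- nchar(seq_fwd)
    found <- NULL
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq_fwd else revcomp(seq_fwd)
      subj <- Biostrings::DNAString(s)
      up <- .best_flank_match(subj, up_pat, up_max)
      if (is.null(up)) next
      if (up$end >= len) next
      tail_subj <- Biostrings::subseq(subj, up$end + 1L, len)
      dn <- .best_flank_match(tail_subj, dn_pat, dn_max)
      if (is.null(dn)) next
      dn_start <- up$end + dn$start          # in oriented coordinates
      insert <- substr(s, up$end + 1L, dn_start - 1L)
      # oriented 0-based half-open span, mapped back to the original read
      os <- up$end; oe <- dn_start - 1L
      span <- if (strand == "+") c(os, oe) else c(len - oe, len - os)
      found <- tibble(read_id = reads$read_id[i], insert = insert,
                      strand = strand, up_flank_errors = up$edits,
                      down_flank_errors = dn$edits,
                      insert_start = span[1], insert_end = span[2])
      break
    }
    hits[[i]] <- found
  }
  out <- list_rbind(hits[!vapply(hits, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(read_id = character(0), insert = character(0),
                  strand = character(0), up_flank_errors = integer(0),
                  down_flank_errors = integer(0), insert_start = integer(0),
                  insert_end = integer(0))
  }
  structure(out, n_reads = nrow(reads), n_discarded = nrow(reads) - nrow(out),
            class = c("insert_hits", class(out)))
}

#' Assign extracted inserts to unit-count bins
#'
#' Each insert is assigned to the unit count `j` whose expected insert length
#' is closest to the observed length, provided the residual is smaller than
#' half the per-unit length increment; otherwise it is left unbinned (`NA`).
#'
#' @param inserts An `insert_hits` tibble (or any tibble with an `insert`
#'   column).
#' @param design The `array_design` providing the expected length table.
#' @return `inserts` with an added integer `n_units` column.
#' @export
assign_unit_counts <- function(inserts, design) {
  stopifnot(inherits(design, "array_design"))
  tab <- unname(design$unit_length_table)
  increment <- if (length(tab) > 1L) tab[2] - tab[1] else tab[1]
  lens <- nchar(inserts$insert)
  j <- vapply(lens, function(L) {
    jj <- which.min(abs(L - tab))
    if (abs(L - tab[jj]) < increment / 2) jj else NA_integer_
  }, integer(1))
  inserts$n_units <- j
  inserts
}

#' Bin inserts by length into a unit-count histogram
#'
#' @inheritParams assign_unit_counts
#' @return A `gg_length_histogram` tibble with columns `n_units`,
#'   `expected_length`, `count` (one row per unit count `1..k`), and
#'   attributes `n_extracted` and `n_unbinned` satisfying
#'   `sum(count) + n_unbinned = n_extracted`.
#' @export
bin_by_length <- function(inserts, design) {
  assigned <- assign_unit_counts(inserts, design)
  k <- design$k
  counts <- tabulate(assigned$n_units[!is.na(assigned$n_units)], nbins = k)
  out <- tibble(n_units = seq_len(k),
                expected_length = unname(design$unit_length_table),
                count = counts)
  structure(out,
            n_extracted = nrow(assigned),
            n_unbinned = sum(is.na(assigned$n_units)),
            k = k,
            class = c("gg_length_histogram", class(out)))
}

#' @export
glance.gg_length_histogram <- function(x, ...) {
  k <- attr(x, "k")
  n_binned <- sum(x$count)
  tibble(
    n_extracted = attr(x, "n_extracted"),
    n_binned = n_binned,
    n_unbinned = attr(x, "n_unbinned"),
    full_length_count = x$count[x$n_units == k],
    full_length_fraction = if (n_binned > 0) x$count[x$n_units == k] / n_binned
                           else NA_real_
  )
}

#' Alignment scoring parameters
#'
#' @param match,mismatch Per-column scores.
#' @param gap_open,gap_ext Gap penalties (positive; a gap of length L costs
#'   `gap_open + L * gap_ext`).
#' @return A list of scoring parameters.
#' @export
alignment_scoring <- function(match = 1, mismatch = -1, gap_open = 2,
                              gap_ext = 1) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_ext = gap_ext)
}

# Global alignment of query against the expected reference. Returns identity,
# per-column difference calls (unmapped to regions), and the ref->query
# coordinate projection.
.align_to_expected <- function(query, expected, scoring = alignment_scoring()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                                  mismatch = scoring$mismatch)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(expected),
    type = "global", substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
  pc <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sc <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ref_idx <- cumsum(sc != "-")   # per column: number of ref bases consumed
  q_idx <- cumsum(pc != "-")
  identity <- sum(pc == sc & sc != "-") / length(pc)

  calls <- list()
  # substitutions: aligned columns with differing bases
  mm <- which(pc != "-" & sc != "-" & pc != sc)
  if (length(mm)) {
    calls[[1]] <- tibble(kind = "substitution", ref_position = ref_idx[mm] - 1L,
                         length = 1L)
  }
  # insertions in the query: runs of gap columns in the reference
  ins <- which(sc == "-")
  if (length(ins)) {
    runs <- split(ins, cumsum(c(1L, diff(ins) != 1L)))
    calls[[length(calls) + 1L]] <- list_rbind(map(runs, function(r) {
      tibble(kind = "insertion", ref_position = ref_idx[r[1]],
             length = length(r))
    }))
  }
  # deletions from the query: runs of gap columns in the query
  del <- which(pc == "-")
  if (length(del)) {
    runs <- split(del, cumsum(c(1L, diff(del) != 1L)))
    calls[[length(calls) + 1L]] <- list_rbind(map(runs, function(r) {
      tibble(kind = "deletion", ref_position = ref_idx[r[1]] - 1L,
             length = length(r))
    }))
  }
  calls <- if (length(calls)) list_rbind(calls) else {
    tibble(kind = character(0), ref_position = integer(0), length = integer(0))
  }

  ref2query <- rep(NA_integer_, nchar(expected))
  mapped <- which(sc != "-" & pc != "-")
  ref2query[ref_idx[mapped]] <- q_idx[mapped] - 1L   # 0-based query positions
  list(identity = identity, calls = calls, ref2query = ref2query)
}

# map a 0-based reference position to (unit, region) via the insert region map
.locate_region <- function(ref_position, regions) {
  pos <- pmin(pmax(ref_position, 0L), max(regions$end) - 1L)
  idx <- vapply(pos, function(p) {
    which(regions$start <= p & regions$end > p)[1]
  }, integer(1))
  region <- regions$region[idx]
  region[region %in% c("primer_tail_left", "primer_tail_right")] <- "primer_tail"
  tibble(unit = regions$unit[idx], region = region)
}

#' Profile mutations in extracted inserts
#'
#' Globally aligns each insert to the expected array sequence and converts
#' every non-matching column into a mutation call located in the design's
#' region map (adjacent gap columns are merged into a single indel call).
#' A unit is flagged *deleterious-mutated* when it has one or more calls in
#' its U6 promoter, spacer or scaffold; calls confined to primer-tail regions
#' are inconsequential (the tails only serve unit amplification). Inserts
#' aligning below `min_identity` are flagged unalignable and excluded from
#' the per-unit statistics.
#'
#' @param inserts An `insert_hits` tibble, any tibble with `read_id` and
#'   `insert` columns, or a character vector of insert sequences. Inserts
#'   should be full length (or `expected` must be the matching truncated
#'   reference).
#' @param design The `array_design`.
#' @param expected Expected reference sequence; defaults to the design's full
#'   expected insert.
#' @param scoring An [alignment_scoring()] list.
#' @param min_identity Minimum alignment identity below which an insert is
#'   excluded.
#' @return A `mutation_profile` object: `$calls` (tibble `read_id`, `unit`,
#'   `region`, `kind`, `ref_position`, `length`), `$reads` (tibble `read_id`,
#'   `identity`, `alignable`) and `$units` (per read x unit flags
#'   `deleterious`, `tail_only`). `tidy()` returns the calls, `glance()` the
#'   per-unit summary rates.
#' @export
profile_mutations <- function(inserts, design, expected = NULL,
                              scoring = alignment_scoring(),
                              min_identity = 0.8) {
  stopifnot(inherits(design, "array_design"))
  if (is.character(inserts)) {
    inserts <- tibble(read_id = sprintf("insert_%05d", seq_along(inserts)),
                      insert = inserts)
  }
  expected <- expected %||% design$expected_insert
  regions <- design$insert_regions
  k <- design$k

  reads <- vector("list", nrow(inserts))
  calls <- vector("list", nrow(inserts))
  for (i in seq_len(nrow(inserts))) {
    al <- .align_to_expected(inserts$insert[i], expected, scoring)
    alignable <- al$identity >= min_identity
    reads[[i]] <- tibble(read_id = inserts$read_id[i], identity = al$identity,
                         alignable = alignable)
    if (alignable && nrow(al$calls) > 0) {
      loc <- .locate_region(al$calls$ref_position, regions)
      calls[[i]] <- bind_cols(tibble(read_id = inserts$read_id[i]),
                              loc, al$calls)
    }
  }
  reads <- list_rbind(reads)
  calls <- list_rbind(calls[!vapply(calls, is.null, logical(1))])
  if (is.null(calls) || nrow(calls) == 0) {
    calls <- tibble(read_id = character(0), unit = integer(0),
                    region = character(0), kind = character(0),
                    ref_position = integer(0), length = integer(0))
  }

  deleterious_regions <- c("u6_promoter", "spacer", "scaffold")
  aligned_ids <- reads$read_id[reads$alignable]
  units <- tidyr::expand_grid(read_id = aligned_ids, unit = seq_len(k))
  per_unit <- calls |>
    group_by(.data$read_id, .data$unit) |>
    summarise(n_deleterious = sum(.data$region %in% deleterious_regions),
              n_tail = sum(.data$region == "primer_tail"), .groups = "drop")
  units <- units |>
    left_join(per_unit, by = c("read_id", "unit")) |>
    mutate(n_deleterious = dplyr::coalesce(.data$n_deleterious, 0L),
           n_tail = dplyr::coalesce(.data$n_tail, 0L),
           deleterious = .data$n_deleterious > 0L,
           tail_only = .data$n_deleterious == 0L & .data$n_tail > 0L)

  structure(list(calls = calls, reads = reads, units = units, k = k),
            class = "mutation_profile")
}

#' @export
print.mutation_profile <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<mutation profile: %d/%d inserts alignable, %d calls>\n",
              g$n_alignable, g$n_reads, nrow(x$calls)))
  cat(sprintf("  deleterious-mutated units: %d/%d (%.1f%%)\n",
              g$n_deleterious_units, g$n_units,
              100 * g$deleterious_unit_fraction))
  invisible(x)
}

#' @export
tidy.mutation_profile <- function(x, ...) {
  x$calls
}

#' @export
glance.mutation_profile <- function(x, ...) {
  tibble(
    n_reads = nrow(x$reads),
    n_alignable = sum(x$reads$alignable),
    n_units = nrow(x$units),
    n_deleterious_units = sum(x$units$deleterious),
    deleterious_unit_fraction = if (nrow(x$units) > 0)
      mean(x$units$deleterious) else NA_real_,
    n_tail_only_units = sum(x$units$tail_only)
  )
}

#' Map observed spacers of full-length inserts to a known pool
#'
#' For each full-length insert, projects the coordinates of every spacer
#' region through the global alignment against the expected array, extracts
#' the observed spacer window, and assigns it to the pool member with the
#' highest normalised similarity (1 - edit distance / max length) when that
#' best member is unique and reaches `min_identity`; otherwise the window is
#' counted as `unassigned` (ties are never broken arbitrarily).
#'
#' @param inserts An `insert_hits` tibble (only inserts binned at the full
#'   unit count are used) or a character vector of full-length insert
#'   sequences.
#' @param design The `array_design` carrying the per-position pools.
#' @param min_identity Minimum normalised similarity for assignment.
#' @param scoring An [alignment_scoring()] list.
#' @return A `position_spacer_matrix` tibble with columns `position`,
#'   `member`, `count` (the `member` level `unassigned` included); attribute
#'   `n_inserts` is the number of full-length inserts processed, and every
#'   position's counts sum to it.
#' @export
map_spacers <- function(inserts, design, min_identity = 0.8,
                        scoring = alignment_scoring()) {
  stopifnot(inherits(design, "array_design"))
  if (any(vapply(design$pools, nrow, integer(1)) == 0L)) {
    abort("design has an empty spacer pool", class = "guidearray_validation_error")
  }
  if (is.character(inserts)) {
    inserts <- tibble(read_id = sprintf("insert_%05d", seq_along(inserts)),
                      insert = inserts)
  }
  if (!"n_units" %in% names(inserts)) {
    inserts <- assign_unit_counts(inserts, design)
  }
  full <- inserts[!is.na(inserts$n_units) & inserts$n_units == design$k, ]
  k <- design$k
  regions <- design$insert_regions
  spacer_regions <- regions[regions$region == "spacer", ]
  members <- unique(unlist(lapply(design$pools, function(p) p$name)))
  levels <- c(members, "unassigned")
  counts <- matrix(0L, nrow = k, ncol = length(levels),
                   dimnames = list(position = seq_len(k), member = levels))

  for (i in seq_len(nrow(full))) {
    al <- .align_to_expected(full$insert[i], design$expected_insert, scoring)
    for (p in seq_len(k)) {
      s <- spacer_regions$start[spacer_regions$unit == p]
      e <- spacer_regions$end[spacer_regions$unit == p]
      qpos <- al$ref2query[(s + 1L):e]
      qpos <- qpos[!is.na(qpos)]
      assigned <- "unassigned"
      if (length(qpos) > 0) {
        window <- substr(full$insert[i], min(qpos) + 1L, max(qpos) + 1L)
        pool <- design$pools[[p]]
        d <- as.integer(adist(window, toupper(pool$spacer)))
        sim <- 1 - d / pmax(nchar(window), nchar(pool$spacer))
        best <- max(sim)
        if (best >= min_identity && sum(sim == best) == 1L) {
          assigned <- pool$name[which.max(sim)]
        }
      }
      counts[p, assigned] <- counts[p, assigned] + 1L
    }
  }

  out <- as_tibble(as.data.frame.table(counts, responseName = "count",
                                       stringsAsFactors = FALSE)) |>
    mutate(position = as.integer(.data$position)) |>
    arrange(.data$position, .data$member)
  structure(out, n_inserts = nrow(full), matrix = counts,
            class = c("position_spacer_matrix", class(out)))
}

#' Summarise a QC run
#'
#' Combines the outputs of the QC stages into the headline numbers: the
#' full-length fraction among binned inserts and the deleterious per-unit
#' mutation rate.
#'
#' @param histogram A `gg_length_histogram`.
#' @param profile Optional `mutation_profile`.
#' @return A one-row tibble.
#' @export
qc_summary <- function(histogram, profile = NULL) {
  h <- glance(histogram)
  out <- tibble(
    n_reads_extracted = h$n_extracted,
    n_binned = h$n_binned,
    n_unbinned = h$n_unbinned,
    full_length_count = h$full_length_count,
    full_length_fraction = h$full_length_fraction
  )
  if (!is.null(profile)) {
    g <- glance(profile)
    out$n_units_profiled <- g$n_units
    out$deleterious_unit_fraction <- g$deleterious_unit_fraction
  }
  out
}
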