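# The array design object: everything needed to order oligos, run the
# assembly, and later check sequencing data against expectation.

# normalise spacer input to a list of per-position pools
.as_pools <- function(spacers) {
  if (is.data.frame(spacers)) {
    need <- c("position", "spacer")
    if (!all(need %in% names(spacers))) {
      abort("spacer data frame needs columns 'position' and 'spacer' (optional 'name', 'weight')",
            class = "guidearray_validation_error")
    }
    df <- as_tibble(spacers)
    if (!"name" %in% names(df)) {
      df$name <- paste0("pos", df$position, "_g", stats::ave(
        seq_len(nrow(df)), df$position, FUN = seq_along))
    }
    if (!"weight" %in% names(df)) df$weight <- 1
    k <- max(df$position)
    if (!setequal(unique(df$position), seq_len(k))) {
      abort("positions must cover 1..k with no gaps",
            class = "guidearray_validation_error")
    }
    pools <- lapply(seq_len(k), function(p) {
      pool <- df[df$position == p, c("name", "spacer", "weight")]
      pool$weight <- pool$weight / sum(pool$weight)
      pool
    })
  } else {
    sp <- as.character(spacers)
    nm <- names(spacers) %||% paste0("g", seq_along(sp))
    if (is.null(names(spacers))) nm <- paste0("g", seq_along(sp))
    pools <- lapply(seq_along(sp), function(p) {
      tibble(name = nm[p], spacer = toupper(sp[p]), weight = 1)
    })
  }
  pools
}

#' Build a complete array design
#'
#' Turns an ordered list of 20-nt spacers (or per-position spacer pools, for
#' array libraries) into the full specification of a Golden Gate gRNA array:
#' spacer oligos, position-specific primers, junction overhangs, the expected
#' PCA product and digested fragment for every unit, the expected assembled
#' insert with a per-unit region map, and the expected (circular) plasmid.
#'
#' @param spacers A character vector of spacers (one per position), or a data
#'   frame with columns `position`, `spacer` and optionally `name`, `weight`
#'   where several rows per position define a pooled-library position.
#' @param fixtures A `gg_fixtures` object.
#' @param overhang_set Optional `overhang_set`; defaults to
#'   [select_overhang_set()] for the requested number of units.
#' @param up_arm_len,down_arm_len Spacer-oligo homology arm lengths.
#' @param anneal_len Primer annealing-region length.
#' @param pad,stuffer Primer tail components (see
#'   [design_position_primers()]).
#' @param max_k Maximum number of units accepted (default 20; a hard ceiling
#'   of 52 applies regardless, with a warning for designs above 20 units).
#' @param check_sites If `FALSE`, skip rejection of internal recognition
#'   sites (useful only for constructing deliberately defective designs to
#'   exercise [validate_design()]).
#' @return An `array_design` object. Key fields: `$oligos`, `$primers`
#'   (tibbles ready to order), `$units` (expected PCA products and digested
#'   fragments), `$expected_insert`, `$insert_regions`, `$unit_length_table`,
#'   `$expected_plasmid`.
#' @export
#' @examples
#' fx <- default_fixtures()
#' spacers <- replicate(3, paste(sample(c("A","C","G","T"), 20, TRUE), collapse = ""))
#' # (in real use these are your guide spacers)
#' des <- try(build_array_design(spacers, fx), silent = TRUE)
build_array_design <- function(spacers, fixtures = default_fixtures(),
                               overhang_set = NULL,
                               up_arm_len = 20L, down_arm_len = 19L,
                               anneal_len = 20L, pad = "AT", stuffer = "A",
                               max_k = 20L, check_sites = TRUE) {
  stopifnot(inherits(fixtures, "gg_fixtures"))
  pools <- .as_pools(spacers)
  k <- length(pools)
  if (k > 52L) {
    abort("at most 52 units can be assembled (junction overhang capacity)",
          class = "guidearray_validation_error")
  }
  if (k > max_k) {
    abort(sprintf("design has %d units but max_k = %d; raise max_k (hard ceiling 52) to proceed",
                  k, max_k), class = "guidearray_validation_error")
  }
  if (k > 20L) {
    warn(sprintf("designs above 20 units (k = %d) are expected to assemble with reduced efficiency", k))
  }
  overhang_set <- overhang_set %||% select_overhang_set(k)
  if (attr(overhang_set, "k") != k) {
    abort(sprintf("overhang set is for k = %d but %d positions were given",
                  attr(overhang_set, "k"), k),
          class = "guidearray_validation_error")
  }
  enzyme <- fixtures$enzyme
  u6 <- fixtures$u6_promoter
  sc <- fixtures$scaffold_terminator
  u6_len <- nchar(u6); sc_len <- nchar(sc)
  if (anneal_len >= u6_len || anneal_len >= sc_len) {
    abort("anneal_len must be shorter than both fixture sequences",
          class = "guidearray_validation_error")
  }

  oligos <- list_rbind(imap(pools, function(pool, p) {
    out <- design_spacer_oligos(pool, fixtures, up_arm_len, down_arm_len,
                                validate_sites = check_sites)
    out$position <- as.integer(p)
    out$weight <- pool$weight
    out[, c("position", "name", "spacer", "up_arm", "down_arm", "sequence",
            "length", "weight")]
  }))
  primers <- design_position_primers(overhang_set, fixtures = fixtures,
                                     anneal_len = anneal_len, pad = pad,
                                     stuffer = stuffer)

  oh <- unclass(overhang_set)
  tail_len <- .tail_len(enzyme, pad)
  ohl <- enzyme$overhang_len
  core_len <- u6_len + 20L + sc_len

  # representative member per position defines the expected sequences
  rep_spacer <- map_chr(pools, function(pool) toupper(pool$spacer[1]))
  rep_name <- map_chr(pools, function(pool) pool$name[1])
  fwd_tail <- paste0(pad, enzyme$recognition, stuffer)
  rev_tail_rc <- paste0(revcomp(stuffer), revcomp(enzyme$recognition),
                        revcomp(pad))
  pca_product <- paste0(fwd_tail, oh[seq_len(k)], u6, rep_spacer, sc,
                        oh[seq_len(k) + 1L], rev_tail_rc)
  fragments <- paste0(oh[seq_len(k)], u6, rep_spacer, sc, oh[seq_len(k) + 1L])
  if (check_sites) {
    # cross-check construction against simulated digestion of each product
    digests <- map(pca_product, .digest_unit, enzyme = enzyme)
    for (p in seq_len(k)) {
      if (digests[[p]]$fragment != fragments[p] ||
          digests[[p]]$left_overhang != oh[p] ||
          digests[[p]]$right_overhang != oh[p + 1L]) {
        abort(sprintf("internal error: digestion of unit %d does not expose the designed overhangs", p))
      }
    }
  }

  # pca_product region map (0-based half-open), tiling the product:
  # primer tails = full primer footprints (5' tail + annealing region)
  pca_len <- nchar(pca_product[1])
  pca_regions <- list_rbind(map(seq_len(k), function(p) {
    tibble(
      position = p,
      region = c("primer_tail_left", "u6_promoter", "spacer", "scaffold",
                 "primer_tail_right"),
      start = c(0L, tail_len + anneal_len, tail_len + u6_len,
                tail_len + u6_len + 20L, tail_len + core_len - anneal_len),
      end = c(tail_len + anneal_len, tail_len + u6_len, tail_len + u6_len + 20L,
              tail_len + core_len - anneal_len, pca_len)
    )
  }))

  # expected insert: junction overhangs counted once; internal junction
  # overhangs are assigned to the downstream unit's left primer tail
  cores <- paste0(u6, rep_spacer, sc)
  expected_insert <- paste0(oh[1], paste0(cores, oh[seq_len(k) + 1L],
                                          collapse = ""))
  insert_regions <- list_rbind(map(seq_len(k), function(p) {
    b <- ohl + (p - 1L) * (core_len + ohl)   # start of unit p's core
    left_start <- if (p == 1L) 0L else b - ohl
    right_end <- if (p == k) b + core_len + ohl else b + core_len
    tibble(
      unit = p,
      region = c("primer_tail_left", "u6_promoter", "spacer", "scaffold",
                 "primer_tail_right"),
      start = c(left_start, b + anneal_len, b + u6_len, b + u6_len + 20L,
                b + core_len - anneal_len),
      end = c(b + anneal_len, b + u6_len, b + u6_len + 20L,
              b + core_len - anneal_len, right_end)
    )
  }))

  unit_length_table <- setNames(
    seq_len(k) * (core_len + ohl) + ohl,
    paste0("units_", seq_len(k))
  )

  if (check_sites) {
    pad_up <- substr(fixtures$vector_flank_up,
                     max(1L, nchar(fixtures$vector_flank_up) - 8L),
                     nchar(fixtures$vector_flank_up))
    pad_dn <- substr(fixtures$vector_flank_down, 1L, 9L)
    scan <- find_recognition_sites(paste0(pad_up, expected_insert, pad_dn),
                                   enzyme)
    if (nrow(scan) > 0) {
      pos <- scan$start - nchar(pad_up)
      abort(sprintf(
        "expected insert contains %s recognition site(s) at insert position(s) %s",
        enzyme$name, paste(pos, collapse = ", ")),
        class = "guidearray_validation_error")
    }
  }

  structure(
    list(
      k = k,
      library_mode = any(vapply(pools, nrow, integer(1)) > 1L),
      fixtures = fixtures,
      overhang_set = overhang_set,
      params = list(up_arm_len = up_arm_len, down_arm_len = down_arm_len,
                    anneal_len = anneal_len, pad = pad, stuffer = stuffer),
      pools = pools,
      oligos = oligos,
      primers = primers,
      units = tibble(position = seq_len(k), name = rep_name,
                     spacer = rep_spacer, pca_product = pca_product,
                     digested_fragment = fragments,
                     fragment_length = nchar(fragments)),
      pca_regions = pca_regions,
      expected_insert = expected_insert,
      insert_regions = insert_regions,
      unit_length_table = unit_length_table,
      expected_plasmid = paste0(fixtures$vector_flank_up, expected_insert,
                                fixtures$vector_flank_down)
    ),
    class = "array_design"
  )
}

#' @export
print.array_design <- function(x, ...) {
  cat(sprintf("<array design: %d unit%s%s>\n", x$k, if (x$k > 1) "s" else "",
              if (x$library_mode) ", pooled library" else ""))
  cat(sprintf("  PCA unit: %d bp; expected insert: %d bp; plasmid: %d bp (circular)\n",
              nchar(x$units$pca_product[1]), nchar(x$expected_insert),
              nchar(x$expected_plasmid)))
  cat(sprintf("  overhangs: %s\n", paste(unclass(x$overhang_set), collapse = " ")))
  invisible(x)
}

#' @export
tidy.array_design <- function(x, ...) {
  x$oligos
}

#' @export
glance.array_design <- function(x, ...) {
  tibble(
    k = x$k,
    library_mode = x$library_mode,
    n_oligos = nrow(x$oligos),
    unit_length = nchar(x$units$pca_product[1]),
    fragment_length = x$units$fragment_length[1],
    insert_length = nchar(x$expected_insert),
    plasmid_length = nchar(x$expected_plasmid)
  )
}

#' Validate an array design against its invariants
#'
#' Checks every structural invariant of an `array_design` and returns the
#' violations as data rather than raising errors: overhang-set constraints
#' (distinctness, palindromes, cross-complements, GC content), junction
#' chaining between adjacent positions, exact reconstructability of the
#' expected insert from the digested fragments, region-map tiling, and the
#' absence of recognition sites anywhere in the expected insert on either
#' strand.
#'
#' @param design An `array_design`.
#' @return A tibble of violations with columns `rule`, `unit`, `position`
#'   (0-based coordinate where applicable) and `message`; zero rows for a
#'   valid design.
#' @export
validate_design <- function(design) {
  stopifnot(inherits(design, "array_design"))
  v <- list()
  add <- function(rule, unit, position, message) {
    v[[length(v) + 1L]] <<- tibble(rule = rule, unit = unit,
                                   position = position, message = message)
  }
  enzyme <- design$fixtures$enzyme
  ohl <- enzyme$overhang_len
  k <- design$k

  ov <- overhang_violations(design$overhang_set, gc_min = 1L, gc_max = 3L,
                            min_hamming = 1L)
  for (i in seq_len(nrow(ov))) {
    add(paste0("overhang_", ov$rule[i]), NA_integer_, ov$index[i] - 1L,
        ov$message[i])
  }

  pr <- design$primers
  if (k > 1L) {
    for (p in seq_len(k - 1L)) {
      if (pr$right_overhang[p] != pr$left_overhang[p + 1L]) {
        add("junction_chaining", p, NA_integer_,
            sprintf("right overhang of unit %d ('%s') differs from left overhang of unit %d ('%s')",
                    p, pr$right_overhang[p], p + 1L, pr$left_overhang[p + 1L]))
      }
    }
  }

  # ligation reconstruction: fragments joined on shared junction overhangs
  frags <- design$units$digested_fragment
  lig <- frags[1]
  ok <- TRUE
  if (k > 1L) {
    for (p in seq(2L, k)) {
      junction <- substr(lig, nchar(lig) - ohl + 1L, nchar(lig))
      if (substr(frags[p], 1L, ohl) != junction) {
        add("ligation_mismatch", p, NA_integer_,
            sprintf("fragment %d does not start with the junction overhang '%s'",
                    p, junction))
        ok <- FALSE
        break
      }
      lig <- paste0(lig, substr(frags[p], ohl + 1L, nchar(frags[p])))
    }
  }
  if (ok && lig != design$expected_insert) {
    add("insert_mismatch", NA_integer_, NA_integer_,
        "expected_insert is not the ligation of the digested fragments")
  }

  # region maps must tile without gaps or overlaps
  for (tab in list(pca = design$pca_regions, insert = design$insert_regions)) {
    key <- if ("position" %in% names(tab)) "position" else "unit"
    ord <- tab[order(tab$start), ]
    if (any(ord$end <= ord$start)) {
      add("region_empty", NA_integer_, NA_integer_, "empty or inverted region")
    }
  }
  ins <- design$insert_regions[order(design$insert_regions$start), ]
  if (ins$start[1] != 0L ||
      ins$end[nrow(ins)] != nchar(design$expected_insert) ||
      (nrow(ins) > 1L && any(ins$start[-1] != ins$end[-nrow(ins)]))) {
    add("region_tiling", NA_integer_, NA_integer_,
        "insert region map does not tile the expected insert")
  }

  # enzyme safety: no recognition site anywhere in the expected insert
  sites <- find_recognition_sites(design$expected_insert, enzyme)
  if (nrow(sites) > 0) {
    for (i in seq_len(nrow(sites))) {
      hit <- ins[ins$start <= sites$start[i] & ins$end > sites$start[i], ]
      unit <- if (nrow(hit)) hit$unit[1] else NA_integer_
      add("recognition_site_in_insert", unit, sites$start[i],
          sprintf("%s site on strand %s at insert position %d%s",
                  enzyme$name, sites$strand[i], sites$start[i],
                  if (!is.na(unit)) sprintf(" (unit %d, %s)", unit, hit$region[1]) else ""))
    }
  }

  # expected unit lengths must follow the digested fragment lengths
  frag_len <- design$units$fragment_length[1]
  expect_len <- seq_len(k) * (frag_len - ohl) + ohl
  if (!all(design$unit_length_table == expect_len)) {
    add("length_table", NA_integer_, NA_integer_,
        "unit_length_table disagrees with the digested fragment lengths")
  }

  if (length(v) == 0) {
    tibble(rule = character(0), unit = integer(0), position = integer(0),
           message = character(0))
  } else {
    list_rbind(v)
  }
}
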