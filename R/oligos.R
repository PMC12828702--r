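#' Design single-stranded spacer oligos
#'
#' Each new gRNA needs only one short single-stranded oligo: the 20-nt spacer
#' flanked by homology arms that let polymerase cycling assembly stitch it
#' between the U6 promoter and the scaffold-terminator. With the default arm
#' lengths (20 nt on the promoter side, 19 nt on the scaffold side) the oligo
#' is 59 nt.
#'
#' @param spacers Spacer sequences: a character vector (optionally named), or
#'   a data frame with columns `name` and `spacer`.
#' @param fixtures A `gg_fixtures` object; defaults to the packaged synthetic
#'   set.
#' @param up_arm_len Homology arm length on the U6-promoter side (a suffix of
#'   the promoter).
#' @param down_arm_len Homology arm length on the scaffold side (a prefix of
#'   the scaffold-terminator).
#' @param validate_sites If `FALSE`, skip recognition-site rejection (used
#'   only to construct deliberately defective designs for
#'   [validate_design()]).
#' @return A tibble with one row per spacer: `name`, `spacer`, `up_arm`,
#'   `down_arm`, `sequence`, `length`.
#' @export
#' @examples
#' design_spacer_oligos(c(g1 = "ACGTACGTACGTACGTACGT"))
design_spacer_oligos <- function(spacers, fixtures = default_fixtures(),
                                 up_arm_len = 20L, down_arm_len = 19L,
                                 validate_sites = TRUE) {
  stopifnot(inherits(fixtures, "gg_fixtures"))
  if (is.data.frame(spacers)) {
    if (!all(c("name", "spacer") %in% names(spacers))) {
      abort("spacer data frame needs columns 'name' and 'spacer'",
            class = "guidearray_validation_error")
    }
    nm <- as.character(spacers$name)
    sp <- toupper(as.character(spacers$spacer))
  } else {
    sp <- toupper(as.character(spacers))
    nm <- names(spacers) %||% paste0("spacer_", seq_along(sp))
    if (is.null(names(spacers))) nm <- paste0("spacer_", seq_along(sp))
  }
  up_arm_len <- as.integer(up_arm_len)
  down_arm_len <- as.integer(down_arm_len)
  if (up_arm_len < 12L || down_arm_len < 12L) {
    abort("homology arms must be at least 12 nt",
          class = "guidearray_validation_error")
  }
  u6 <- fixtures$u6_promoter
  sc <- fixtures$scaffold_terminator
  if (up_arm_len > nchar(u6) || down_arm_len > nchar(sc)) {
    abort("homology arm longer than the corresponding fixture",
          class = "guidearray_validation_error")
  }
  .assert_dna(sp, "spacer")
  bad_len <- which(nchar(sp) != 20L)
  if (length(bad_len)) {
    abort(sprintf("spacer '%s' is %d nt; spacers must be 20 nt",
                  nm[bad_len[1]], nchar(sp[bad_len[1]])),
          class = "guidearray_validation_error")
  }
  enzyme <- fixtures$enzyme
  for (i in if (validate_sites) seq_along(sp) else integer(0)) {
    sites <- find_recognition_sites(sp[i], enzyme)
    if (nrow(sites) > 0) {
      abort(sprintf(
        "spacer '%s' contains a %s recognition site at position %d (%s strand)",
        nm[i], enzyme$name, sites$start[1], sites$strand[1]),
        class = "guidearray_validation_error")
    }
  }
  up_arm <- substr(u6, nchar(u6) - up_arm_len + 1L, nchar(u6))
  down_arm <- substr(sc, 1L, down_arm_len)
  oligo <- paste0(up_arm, sp, down_arm)
  # a site can also arise across an arm/spacer boundary
  for (i in if (validate_sites) seq_along(oligo) else integer(0)) {
    sites <- find_recognition_sites(oligo[i], enzyme)
    if (nrow(sites) > 0) {
      abort(sprintf(
        "oligo for spacer '%s' forms a %s site across an arm boundary (oligo position %d, %s strand)",
        nm[i], enzyme$name, sites$start[1], sites$strand[1]),
        class = "guidearray_validation_error")
    }
  }
  tibble(name = nm, spacer = sp, up_arm = up_arm, down_arm = down_arm,
         sequence = oligo, length = nchar(oligo))
}

#' @rdname design_spacer_oligos
#' @param spacer A single 20-nt spacer sequence.
#' @param name Optional oligo name.
#' @export
design_spacer_oligo <- function(spacer, fixtures = default_fixtures(),
                                up_arm_len = 20L, down_arm_len = 19L,
                                name = "spacer_1") {
  design_spacer_oligos(setNames(spacer, name), fixtures,
                       up_arm_len = up_arm_len, down_arm_len = down_arm_len)
}

#' Design the position-specific primer pair for each array position
#'
#' Every position of the ordered array uses one forward/reverse primer pair.
#' The 5' tail of each primer carries a short pad (type IIS enzymes cut poorly
#' at blunt ends), the recognition site, the cut spacer, and the junction
#' overhang; the 3' end anneals to the constant fixture sequence (the start of
#' the U6 promoter for the forward primer, the end of the scaffold-terminator
#' for the reverse primer). Digesting the PCA product with the configured
#' enzyme therefore exposes `overhangs[p]` on the left and `overhangs[p + 1]`
#' on the right of position `p`, which is what enforces assembly order.
#'
#' @param overhang_set An `overhang_set` from [select_overhang_set()].
#' @param positions Which positions to design (default: all `k`).
#' @param fixtures A `gg_fixtures` object.
#' @param anneal_len Length of the fixture-annealing region.
#' @param pad 5' pad sequence ahead of the recognition site.
#' @param stuffer Base(s) filling the cut spacer between recognition site and
#'   overhang.
#' @return A tibble with columns `position`, `left_overhang`, `right_overhang`,
#'   `fwd`, `rev`.
#' @export
design_position_primers <- function(overhang_set, positions = NULL,
                                    fixtures = default_fixtures(),
                                    anneal_len = 20L, pad = "AT",
                                    stuffer = "A") {
  stopifnot(inherits(overhang_set, "overhang_set"),
            inherits(fixtures, "gg_fixtures"))
  k <- attr(overhang_set, "k")
  positions <- as.integer(positions %||% seq_len(k))
  if (any(positions < 1L | positions > k)) {
    abort(sprintf("positions must lie in 1..%d for this overhang set", k),
          class = "guidearray_validation_error")
  }
  enzyme <- fixtures$enzyme
  if (nchar(stuffer) != enzyme$cut_spacer) {
    abort("stuffer length must equal the enzyme's cut spacer",
          class = "guidearray_validation_error")
  }
  u6 <- fixtures$u6_promoter
  sc <- fixtures$scaffold_terminator
  fwd_anneal <- substr(u6, 1L, anneal_len)
  rev_anneal_top <- substr(sc, nchar(sc) - anneal_len + 1L, nchar(sc))
  for (region in c(fwd_anneal, rev_anneal_top)) {
    if (nrow(find_recognition_sites(region, enzyme)) > 0) {
      abort("primer annealing region contains a recognition site",
            class = "guidearray_validation_error")
    }
  }
  oh <- unclass(overhang_set)
  tibble(
    position = positions,
    left_overhang = oh[positions],
    right_overhang = oh[positions + 1L],
    fwd = paste0(pad, enzyme$recognition, stuffer, oh[positions], fwd_anneal),
    rev = paste0(pad, enzyme$recognition, stuffer, revcomp(oh[positions + 1L]),
                 revcomp(rev_anneal_top))
  )
}
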