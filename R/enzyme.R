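#' Type IIS enzyme descriptors
#'
#' A type IIS restriction enzyme is modelled by its recognition sequence, the
#' number of bases between the recognition site and the cut on the top strand
#' (`cut_spacer`), and the length of the 5' overhang it exposes. `bsai()`
#' returns the default descriptor used throughout the package: recognition
#' `GGTCTC`, a 1-nt spacer, and a 4-nt 5' overhang (`GGTCTC N^NNNN`).
#'
#' @param recognition Recognition sequence on the top strand, 5'->3'.
#' @param cut_spacer Bases between the recognition site and the top-strand cut.
#' @param overhang_len Length of the exposed 5' overhang.
#' @param name Display name.
#' @return An object of class `type2s_enzyme`.
#' @export
#' @examples
#' bsai()
type2s_enzyme <- function(recognition, cut_spacer = 1L, overhang_len = 4L,
                          name = "enzyme") {
  .assert_dna(recognition, "recognition sequence")
  structure(
    list(name = name,
         recognition = toupper(recognition),
         cut_spacer = as.integer(cut_spacer),
         overhang_len = as.integer(overhang_len)),
    class = "type2s_enzyme"
  )
}

#' @rdname type2s_enzyme
#' @export
bsai <- function() {
  type2s_enzyme("GGTCTC", cut_spacer = 1L, overhang_len = 4L, name = "BsaI")
}

#' @export
print.type2s_enzyme <- function(x, ...) {
  cat(sprintf("<type IIS enzyme %s: %s(%d/%d), %d-nt 5' overhang>\n",
              x$name, x$recognition, x$cut_spacer,
              x$cut_spacer + x$overhang_len, x$overhang_len))
  invisible(x)
}

#' Locate type IIS recognition sites on both strands
#'
#' Scans a sequence for recognition sites of `enzyme` on the top strand and on
#' the bottom strand (reported in top-strand coordinates).
#'
#' @param x DNA string to scan.
#' @param enzyme A [type2s_enzyme()] descriptor.
#' @return A tibble with columns `strand` (`+`/`-`) and `start` (0-based
#'   position of the recognition site's leftmost base in top-strand
#'   coordinates).
#' @export
find_recognition_sites <- function(x, enzyme = bsai()) {
  stopifnot(inherits(enzyme, "type2s_enzyme"))
  top <- .find_fixed(x, enzyme$recognition)
  bot <- .find_fixed(x, revcomp(enzyme$recognition))
  tibble(
    strand = c(rep("+", length(top)), rep("-", length(bot))),
    start = c(top, bot)
  ) |> arrange(.data$start)
}

# Simulate digestion of a linear PCA product carrying one top-strand site on
# the left and one bottom-strand site on the right. Returns the retained
# middle fragment written as its top strand *including* both 4-nt overhangs,
# plus the overhang sequences (top strand, 5'->3').
.digest_unit <- function(pca_product, enzyme = bsai()) {
  sites <- find_recognition_sites(pca_product, enzyme)
  top <- sites$start[sites$strand == "+"]
  bot <- sites$start[sites$strand == "-"]
  if (length(top) != 1L || length(bot) != 1L) {
    abort(sprintf(
      "expected exactly one recognition site per strand; found %d on '+', %d on '-'",
      length(top), length(bot)), class = "guidearray_validation_error")
  }
  rec <- nchar(enzyme$recognition)
  frag_start <- top + rec + enzyme$cut_spacer            # 0-based
  frag_end <- bot - enzyme$cut_spacer                    # half-open
  if (frag_end - frag_start < 2L * enzyme$overhang_len) {
    abort("digestion leaves no fragment between the two cut sites",
          class = "guidearray_validation_error")
  }
  fragment <- substr(pca_product, frag_start + 1L, frag_end)
  list(
    fragment = fragment,
    left_overhang = substr(fragment, 1L, enzyme$overhang_len),
    right_overhang = substr(fragment, nchar(fragment) - enzyme$overhang_len + 1L,
                            nchar(fragment)),
    start = frag_start,
    end = frag_end
  )
}
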