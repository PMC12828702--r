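#' Candidate 4-nt junction overhangs
#'
#' Deterministic, ordered pool of candidate 4-mers used by
#' [select_overhang_set()]. The ordering puts a maximal Hamming-distance-2
#' code first (all 4-mers whose base indices sum to 0 mod 4 — any two such
#' words differ in at least two positions), then the remaining 4-mers, each
#' block in lexicographic order. A greedy scan over this ordering recovers
#' large constraint-satisfying sets without any randomness.
#'
#' @return Character vector of 256 4-mers in a fixed order.
#' @export
overhang_candidates <- function() {
  grid <- expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, DNA_BASES,
                      stringsAsFactors = FALSE)[, 4:1]
  all4 <- sort(apply(grid, 1, paste, collapse = ""))
  idx <- vapply(strsplit(all4, ""), function(b) {
    sum(match(b, DNA_BASES) - 1L) %% 4L
  }, integer(1))
  c(all4[idx == 0L], all4[idx != 0L])
}

#' Check a set of junction overhangs against ligation-fidelity constraints
#'
#' The constraints mirror what makes a Golden Gate junction set high-fidelity:
#' pairwise distinct overhangs, no palindromes (an overhang equal to its own
#' reverse complement ligates to itself), no cross-complementary pairs
#' (overhang i equal to the reverse complement of overhang j would scramble
#' order), GC content within bounds, and a minimum pairwise Hamming distance
#' to suppress mismatch ligation.
#'
#' @param overhangs Character vector of 4-mers.
#' @param gc_min,gc_max Inclusive bounds on G+C count per overhang.
#' @param min_hamming Minimum pairwise Hamming distance.
#' @return A tibble of violations with columns `rule`, `index`, `other`,
#'   `message`; zero rows when the set satisfies every constraint.
#' @export
overhang_violations <- function(overhangs, gc_min = 1L, gc_max = 3L,
                                min_hamming = 2L) {
  v <- list()
  add <- function(rule, index, other, message) {
    v[[length(v) + 1L]] <<- tibble(rule = rule, index = index,
                                   other = other, message = message)
  }
  n <- length(overhangs)
  bad_len <- which(nchar(overhangs) != 4L | !.is_dna(overhangs))
  for (i in bad_len) add("not_4mer", i, NA_integer_,
                         sprintf("'%s' is not a 4-nt A/C/G/T word", overhangs[i]))
  gc <- .gc_count(overhangs)
  for (i in which(gc < gc_min | gc > gc_max)) {
    add("gc_content", i, NA_integer_,
        sprintf("'%s' has %d G/C bases (allowed %d-%d)",
                overhangs[i], gc[i], gc_min, gc_max))
  }
  rcs <- revcomp(overhangs)
  for (i in which(overhangs == rcs)) {
    add("palindrome", i, NA_integer_,
        sprintf("'%s' is its own reverse complement", overhangs[i]))
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (overhangs[i] == overhangs[j]) {
          add("duplicate", i, j,
              sprintf("overhangs %d and %d are both '%s'", i, j, overhangs[i]))
        }
        if (overhangs[i] == rcs[j]) {
          add("cross_complement", i, j,
              sprintf("overhang %d ('%s') is the reverse complement of overhang %d ('%s')",
                      i, overhangs[i], j, overhangs[j]))
        }
        if (overhangs[i] != overhangs[j] &&
            .hamming(overhangs[i], overhangs[j]) < min_hamming) {
          add("hamming_distance", i, j,
              sprintf("overhangs %d ('%s') and %d ('%s') differ at fewer than %d positions",
                      i, overhangs[i], j, overhangs[j], min_hamming))
        }
      }
    }
  }
  if (length(v) == 0) {
    tibble(rule = character(0), index = integer(0), other = integer(0),
           message = character(0))
  } else {
    list_rbind(v)
  }
}

#' Select an ordered set of junction overhangs for a k-unit array
#'
#' Greedily selects `k + 1` distinct 4-nt overhangs (the two vector junctions
#' plus the `k - 1` internal unit junctions) from an ordered candidate pool,
#' keeping each candidate that satisfies all constraints against those already
#' chosen. The scan order is fixed, so the result is deterministic for fixed
#' inputs.
#'
#' @param k Number of units in the array (1 to 52).
#' @param candidates Optional ordered character vector of candidate 4-mers;
#'   defaults to [overhang_candidates()].
#' @inheritParams overhang_violations
#' @return An `overhang_set`: a character vector of `k + 1` overhangs
#'   (element 1 is the vector-left junction, element `k + 1` the vector-right
#'   junction) with attribute `k`.
#' @export
#' @examples
#' select_overhang_set(10)
select_overhang_set <- function(k, candidates = NULL, gc_min = 1L, gc_max = 3L,
                                min_hamming = 2L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 52L) {
    abort("k must be between 1 and 52", class = "guidearray_validation_error")
  }
  candidates <- candidates %||% overhang_candidates()
  if (length(candidates) < k + 1L) {
    abort(sprintf("need at least %d candidates for k = %d, got %d",
                  k + 1L, k, length(candidates)),
          class = "guidearray_validation_error")
  }
  candidates <- toupper(candidates)
  .assert_dna(candidates, "overhang candidates")
  sel <- character(0)
  sel_rc <- character(0)
  for (cand in candidates) {
    if (length(sel) == k + 1L) break
    if (nchar(cand) != 4L) next
    gc <- .gc_count(cand)
    if (gc < gc_min || gc > gc_max) next
    rc <- revcomp(cand)
    if (cand == rc) next
    if (cand %in% sel || cand %in% sel_rc) next
    if (length(sel) &&
        any(vapply(sel, .hamming, integer(1), b = cand) < min_hamming)) next
    sel <- c(sel, cand)
    sel_rc <- c(sel_rc, rc)
  }
  if (length(sel) < k + 1L) {
    abort(sprintf(paste0(
      "cannot select %d overhangs for k = %d under constraints ",
      "(GC %d-%d, non-palindromic, no cross-complements, min Hamming %d): ",
      "only %d candidates qualify; relax min_hamming or supply more candidates"),
      k + 1L, k, gc_min, gc_max, min_hamming, length(sel)),
      class = "guidearray_infeasible_error")
  }
  structure(sel, k = k, class = c("overhang_set", "character"))
}

#' @export
print.overhang_set <- function(x, ...) {
  cat(sprintf("<overhang set for k = %d units (%d junctions)>\n",
              attr(x, "k"), length(x)))
  cat(" ", paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}
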