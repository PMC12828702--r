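# Fixture sequences: the constant parts every gRNA unit is built from (U6
# promoter, scaffold-terminator) plus the destination-vector sequence flanking
# the insert site. Real workflows load these from FASTA; the package also ships
# a synthetic stand-in set whose lengths reproduce the standard 433-bp PCA unit.

.pkg_env <- new.env(parent = emptyenv())

new_fixtures <- function(u6_promoter, scaffold_terminator, vector_flank_up,
                         vector_flank_down, enzyme = bsai()) {
  seqs <- c(u6_promoter = u6_promoter, scaffold_terminator = scaffold_terminator,
            vector_flank_up = vector_flank_up, vector_flank_down = vector_flank_down)
  seqs[] <- toupper(seqs)
  .assert_dna(seqs, "fixture sequence")
  for (nm in c("u6_promoter", "scaffold_terminator")) {
    sites <- find_recognition_sites(seqs[[nm]], enzyme)
    if (nrow(sites) > 0) {
      abort(sprintf("%s contains a %s recognition site at position %d (%s strand)",
                    nm, enzyme$name, sites$start[1], sites$strand[1]),
            class = "guidearray_validation_error")
    }
  }
  structure(
    list(u6_promoter = seqs[["u6_promoter"]],
         scaffold_terminator = seqs[["scaffold_terminator"]],
         vector_flank_up = seqs[["vector_flank_up"]],
         vector_flank_down = seqs[["vector_flank_down"]],
         enzyme = enzyme),
    class = "gg_fixtures"
  )
}

#' @export
print.gg_fixtures <- function(x, ...) {
  cat("<gRNA array fixtures>\n")
  cat(sprintf("  u6_promoter:         %d nt\n", nchar(x$u6_promoter)))
  cat(sprintf("  scaffold_terminator: %d nt\n", nchar(x$scaffold_terminator)))
  cat(sprintf("  vector flanks:       %d / %d nt\n",
              nchar(x$vector_flank_up), nchar(x$vector_flank_down)))
  cat(sprintf("  enzyme:              %s (%s)\n", x$enzyme$name,
              x$enzyme$recognition))
  invisible(x)
}

# length of one primer 5' tail: pad + recognition + cut spacer + overhang
.tail_len <- function(enzyme, pad) {
  nchar(pad) + nchar(enzyme$recognition) + enzyme$cut_spacer + enzyme$overhang_len
}

# context strings that must stay free of unintended recognition sites for any
# candidate overhang: junctions between fixtures/flanks and the primer tails
.fixture_contexts <- function(u6, scaffold, flank_up, flank_down, enzyme,
                              pad, stuffer, overhang) {
  u6_head <- substr(u6, 1, 9)
  sc_tail <- substr(scaffold, nchar(scaffold) - 8, nchar(scaffold))
  fu_tail <- substr(flank_up, nchar(flank_up) - 8, nchar(flank_up))
  fd_head <- substr(flank_down, 1, 9)
  fwd_tail <- paste0(pad, enzyme$recognition, stuffer, overhang)
  rev_tail_rc <- paste0(overhang, revcomp(stuffer), revcomp(enzyme$recognition),
                        revcomp(pad))
  list(
    junction = paste0(sc_tail, overhang, u6_head),
    flank_up_junction = paste0(fu_tail, overhang, u6_head),
    flank_down_junction = paste0(sc_tail, overhang, fd_head),
    fwd_tail = paste0(fwd_tail, u6_head),
    rev_tail = paste0(sc_tail, rev_tail_rc)
  )
}

.contexts_clean <- function(u6, scaffold, flank_up, flank_down, enzyme,
                            pad, stuffer, candidates) {
  u6_head <- substr(u6, 1, 9)
  sc_tail <- substr(scaffold, nchar(scaffold) - 8, nchar(scaffold))
  fu_tail <- substr(flank_up, nchar(flank_up) - 8, nchar(flank_up))
  fd_head <- substr(flank_down, 1, 9)
  fwd_tail <- paste0(pad, enzyme$recognition, stuffer)
  rev_tail_rc <- paste0(revcomp(stuffer), revcomp(enzyme$recognition),
                        revcomp(pad))
  n_cand <- length(candidates)
  # concatenate same-kind contexts with a non-base separator so one scan
  # covers all candidates; the two tail blocks carry exactly one intended
  # site per candidate
  count <- function(x, pattern) {
    hits <- gregexpr(pattern, x, fixed = TRUE)[[1]]
    if (hits[1] == -1) 0L else length(hits)
  }
  rec <- enzyme$recognition
  rcrec <- revcomp(rec)
  plain <- paste(c(paste0(sc_tail, candidates, u6_head),
                   paste0(fu_tail, candidates, u6_head),
                   paste0(sc_tail, candidates, fd_head)), collapse = "X")
  fwd_block <- paste(paste0(fwd_tail, candidates, u6_head), collapse = "X")
  rev_block <- paste(paste0(sc_tail, candidates, rev_tail_rc), collapse = "X")
  count(plain, rec) == 0L && count(plain, rcrec) == 0L &&
    count(fwd_block, rec) == n_cand && count(fwd_block, rcrec) == 0L &&
    count(rev_block, rcrec) == n_cand && count(rev_block, rec) == 0L
}

#' Generate synthetic fixture sequences
#'
#' Draws random recognition-site-free stand-ins for the U6 promoter, the gRNA
#' scaffold-terminator and the two destination-vector flanks, sized so that a
#' default-parameter PCA unit built on them has length `unit_length_target`
#' (433 bp by default, the standard unit size this workflow is verified
#' against on a gel). The generator additionally rejects draws whose
#' junction or primer-tail contexts could form an unintended recognition site
#' with *any* candidate overhang, so every overhang set works with the
#' returned fixtures.
#'
#' These are synthetic sequences for desk-scale design and testing; for real
#' cloning, load the true vector sequences with [read_fixtures()].
#'
#' @param seed Integer seed; fully determines the output.
#' @param unit_length_target Desired PCA product length in bp.
#' @param u6_length Length of the U6 stand-in; default splits the available
#'   length roughly as a real human U6 promoter would (about 68%).
#' @param flank_length Length of each vector flank.
#' @param enzyme A [type2s_enzyme()].
#' @param pad,stuffer Primer 5' pad and cut-spacer base used by the primer
#'   designer (needed to vet tail contexts).
#' @return A `gg_fixtures` object.
#' @export
#' @examples
#' fx <- make_fixtures(seed = 1)
#' nchar(fx$u6_promoter)
make_fixtures <- function(seed, unit_length_target = 433L, u6_length = NULL,
                          flank_length = 200L, enzyme = bsai(),
                          pad = "AT", stuffer = "A") {
  tail_len <- .tail_len(enzyme, pad)
  const_len <- unit_length_target - 20L - 2L * tail_len
  if (const_len < 80L) {
    abort(sprintf(
      "unit_length_target = %d is infeasible: fixtures would total %d nt (< 80)",
      unit_length_target, const_len), class = "guidearray_infeasible_error")
  }
  u6_length <- as.integer(u6_length %||% round(const_len * 0.685))
  sc_length <- const_len - u6_length
  if (u6_length < 40L || sc_length < 40L) {
    abort("u6_length leaves less than 40 nt for the promoter or scaffold",
          class = "guidearray_infeasible_error")
  }
  candidates <- overhang_candidates()
  set.seed(as.integer(seed))
  repeat {
    u6 <- .random_dna(u6_length)
    sc <- .random_dna(sc_length)
    fu <- .random_dna(flank_length)
    fd <- .random_dna(flank_length)
    clean <- all(vapply(list(u6, sc, fu, fd), function(s) {
      nrow(find_recognition_sites(s, enzyme)) == 0L
    }, logical(1)))
    if (!clean) next
    if (.contexts_clean(u6, sc, fu, fd, enzyme, pad, stuffer, candidates)) break
  }
  new_fixtures(u6, sc, fu, fd, enzyme)
}

#' Packaged default fixtures
#'
#' Loads the synthetic fixture set shipped with the package
#' (`extdata/synthetic_fixtures.fasta`), generated once with
#' [make_fixtures()] and frozen so that default designs are byte-stable.
#'
#' @return A `gg_fixtures` object whose default PCA unit is 433 bp.
#' @export
default_fixtures <- function() {
  if (is.null(.pkg_env$default_fixtures)) {
    path <- system.file("extdata", "synthetic_fixtures.fasta",
                        package = "guidearray", mustWork = TRUE)
    .pkg_env$default_fixtures <- read_fixtures(path)
  }
  .pkg_env$default_fixtures
}

#' Read fixture sequences from FASTA
#'
#' The FASTA must contain records named `u6_promoter`, `scaffold_terminator`,
#' `vector_flank_up` and `vector_flank_down`.
#'
#' @param path FASTA file path.
#' @param enzyme A [type2s_enzyme()].
#' @return A `gg_fixtures` object.
#' @export
read_fixtures <- function(path, enzyme = bsai()) {
  if (!file.exists(path)) {
    abort(sprintf("fixture FASTA not found: %s", path),
          class = "guidearray_missing_input_error")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  required <- c("u6_promoter", "scaffold_terminator", "vector_flank_up",
                "vector_flank_down")
  missing <- setdiff(required, ids)
  if (length(missing)) {
    abort(sprintf("fixture FASTA lacks required records: %s",
                  paste(missing, collapse = ", ")),
          class = "guidearray_validation_error")
  }
  s <- setNames(as.character(seqs), ids)
  new_fixtures(s[["u6_promoter"]], s[["scaffold_terminator"]],
               s[["vector_flank_up"]], s[["vector_flank_down"]], enzyme)
}

#' Write fixture sequences to FASTA
#'
#' @param fixtures A `gg_fixtures` object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fixtures <- function(fixtures, path) {
  stopifnot(inherits(fixtures, "gg_fixtures"))
  seqs <- Biostrings::DNAStringSet(c(
    u6_promoter = fixtures$u6_promoter,
    scaffold_terminator = fixtures$scaffold_terminator,
    vector_flank_up = fixtures$vector_flank_up,
    vector_flank_down = fixtures$vector_flank_down
  ))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
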