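# Independent string oracles used to cross-check the implementation, written
# deliberately with base-R string tools only (no shared code paths with R/).

orc_revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(lapply(strsplit(s, ""), rev), paste, character(1), collapse = ""))
}

# digestion oracle: locate GGTCTC on the top strand and GAGACC (the bottom
# strand site) by regex, apply the BsaI cut arithmetic, return the middle
# fragment written with both 4-nt overhangs
orc_digest <- function(pca, rec = "GGTCTC", cut_spacer = 1, ohl = 4) {
  top <- regexpr(rec, pca, fixed = TRUE)[1]
  bot <- regexpr(orc_revcomp(rec), pca, fixed = TRUE)[1]
  stopifnot(top > 0, bot > 0)
  frag_start <- top + nchar(rec) + cut_spacer        # 1-based
  frag_end <- bot - 1 - cut_spacer                   # 1-based inclusive
  frag <- substr(pca, frag_start, frag_end)
  list(fragment = frag,
       left = substr(frag, 1, ohl),
       right = substr(frag, nchar(frag) - ohl + 1, nchar(frag)))
}

# ligation oracle: join fragments that share a 4-bp junction, counting each
# junction once
orc_ligate <- function(fragments, ohl = 4) {
  out <- fragments[1]
  for (f in fragments[-1]) {
    stopifnot(substr(f, 1, ohl) ==
                substr(out, nchar(out) - ohl + 1, nchar(out)))
    out <- paste0(out, substr(f, ohl + 1, nchar(f)))
  }
  out
}

# deterministic spacer sets that pass design validation (resampled until the
# built design is clean, so property tests never trip on a chance BsaI site
# spanning an arm boundary)
clean_spacers <- function(k, fixtures = default_fixtures(), seed = 1) {
  set.seed(seed)
  sp <- character(0)
  while (length(sp) < k) {
    cand <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                  collapse = "")
    ok <- tryCatch({
      design_spacer_oligos(cand, fixtures)
      TRUE
    }, error = function(e) FALSE)
    if (ok) sp <- c(sp, cand)
  }
  setNames(sp, paste0("g", seq_len(k)))
}

test_design <- function(k, seed = 1, fixtures = default_fixtures(), ...) {
  build_array_design(clean_spacers(k, fixtures, seed), fixtures,
                     max_k = 52, ...)
}

# pooled-library design: m spacers in each of k positions
test_library_design <- function(k, m, seed = 1,
                                fixtures = default_fixtures()) {
  sp <- clean_spacers(m, fixtures, seed)
  df <- tibble::tibble(
    position = rep(seq_len(k), each = m),
    name = rep(names(sp), k),
    spacer = rep(unname(sp), k)
  )
  build_array_design(df, fixtures, max_k = 52)
}
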