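# Internal sequence helpers. All coordinates in this package are 0-based
# half-open unless a format (GenBank, FASTQ) dictates otherwise; overhangs are
# always written as top-strand 5'->3'.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character DNA sequences
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] operating
#' on plain character vectors.
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("GGTCTC")
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.is_dna <- function(x) {
  grepl("^[ACGT]+$", x)
}

.assert_dna <- function(x, what = "sequence") {
  bad <- !.is_dna(x)
  if (any(bad)) {
    abort(sprintf("%s contains characters other than A/C/G/T: %s",
                  what, paste(utils::head(x[bad], 3), collapse = ", ")),
          class = "guidearray_validation_error")
  }
  invisible(x)
}

# random DNA string of length n from the current RNG stream
.random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# all start positions (0-based) of fixed pattern in subject
.find_fixed <- function(subject, pattern) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
}

.gc_count <- function(x) {
  vapply(strsplit(x, ""), function(b) sum(b %in% c("G", "C")), integer(1))
}

.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# derive a stream of sub-seeds from one master seed, staying far below 2^31
.subseeds <- function(seed, n) {
  (as.integer(seed) %% 1000000L) * 1000L + seq_len(n)
}
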