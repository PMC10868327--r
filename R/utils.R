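#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet A/C/G/T (anything else,
#' including N, maps to N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' rc_dna(c("ACGT", "AAAC"))
rc_dna <- function(x) {
  if (length(x) == 0L) return(character(0))
  .revcomp_cpp(as.character(x))
}

#' Generate random DNA sequences
#'
#' @param n number of sequences.
#' @param len length of each sequence (recycled).
#' @return character vector of `n` sequences.
#' @export
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# split a DNA string into a character vector of bases (cached-friendly helper)
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

`%||%` <- function(a, b) if (is.null(a)) b else a
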