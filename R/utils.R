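#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over `{A,C,G,T,N}` (case-insensitive;
#' anything unrecognised becomes `N`).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  .revcomp_cpp(toupper(x))
}

#' Random DNA sequences
#'
#' Uniform i.i.d. bases; used by the synthetic generator. Draws from the
#' current RNG stream, so results are reproducible under `set.seed()`.
#'
#' @param n number of sequences.
#' @param len length of each sequence (recycled against `n`).
#' @return character vector of `n` sequences.
#' @export
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# Per-base tabulation of one sequence; returns named integer vector
# c(A=, C=, G=, T=, N=). Bases outside the alphabet count as N.
base_counts <- function(seq) {
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  b[!b %in% c("A", "C", "G", "T")] <- "N"
  tab <- table(factor(b, levels = c("A", "C", "G", "T", "N")))
  stats::setNames(as.integer(tab), names(tab))
}

# Levenshtein distance with N-never-matches semantics (C++ backend).
edit_distance <- function(a, b) .edit_distance_cpp(a, b)

`%||%` <- function(x, y) if (is.null(x)) y else x

# Empty probe-hit table with the canonical columns.
empty_hits <- function() {
  data.frame(start = integer(0), end = integer(0),
             strand = character(0), edits = integer(0),
             stringsAsFactors = FALSE)
}
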