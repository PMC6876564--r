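#' Find approximate occurrences of a probe in a read
#'
#' Semi-global (infix) matching of a short probe against a read and its
#' reverse complement, allowing up to `max_edits` Levenshtein edits
#' (substitutions and indels combined). `N` bases never match. Among
#' overlapping candidate placements the lowest-edit one is kept (ties:
#' leftmost start, then shortest span); surviving hits are non-overlapping
#' and reported in ascending order of `start` on the forward sequence.
#'
#' @param sequence a single DNA string to search.
#' @param probe a single DNA probe (non-empty). A probe longer than the
#'   sequence yields zero hits.
#' @param max_edits maximum edit distance (default 2, the usual barcode
#'   tolerance for 22-nt demultiplexing probes).
#' @param both_strands search the reverse complement too (default `TRUE`).
#'   Minus-strand hits are reported in forward-sequence coordinates with
#'   `strand == "-"`.
#' @return data.frame with columns `start`, `end` (1-based inclusive,
#'   forward coordinates), `strand` (`"+"`/`"-"`) and `edits`.
#' @examples
#' find_probe(paste0("TTTT", "ACGTACGTAC", "GGGG"), "ACGTACGTAC")
#' @export
find_probe <- function(sequence, probe, max_edits = 2L, both_strands = TRUE) {
  stopifnot(length(sequence) == 1L, length(probe) == 1L,
            nzchar(probe), max_edits >= 0L)
  if (nchar(probe) > nchar(sequence)) return(empty_hits())
  df <- scan_probes(sequence, probe, max_edits, both_strands)
  df[c("start", "end", "strand", "edits")]
}

# Batched scan: every pattern against every subject in one C++ call.
# Returns data.frame(subject, pattern, start, end, strand, edits) with
# 1-based indices into the input vectors.
scan_probes <- function(subjects, patterns, max_edits = 2L,
                        both_strands = TRUE) {
  res <- .probe_scan_cpp(subjects, patterns, as.integer(max_edits),
                         both_strands)
  res$strand <- c("-", "+")[(res$strand > 0L) + 1L]
  structure(res, class = "data.frame",
            row.names = .set_row_names(length(res$start)))
}

#' Construct a demultiplexing probe set
#'
#' A probe set holds one probe per sample (by convention a 22-mer: the
#' 16-nt sample barcode followed by the first 6 nt of the
#' template-switching oligo), the shared 5' cDNA primer, and the edit
#' tolerance. Probes whose pairwise edit distance is `<= 2 * max_edits`
#' cannot be told apart at the stated tolerance, so a warning is issued.
#'
#' @param barcode_id character vector of unique sample identifiers.
#' @param probe character vector of equal-length probe sequences, one per
#'   sample.
#' @param five_prime_primer the shared 5' cDNA primer sequence (may be
#'   `NA` to disable 5'-primer trimming).
#' @param max_edits edit tolerance used throughout demultiplexing
#'   (default 2).
#' @return an object of class `probe_set`.
#' @export
probe_set <- function(barcode_id, probe, five_prime_primer = NA_character_,
                      max_edits = 2L) {
  stopifnot(length(barcode_id) == length(probe), length(barcode_id) >= 1L)
  if (anyDuplicated(barcode_id))
    stop("barcode_id values must be unique")
  probe <- toupper(probe)
  if (length(unique(nchar(probe))) != 1L)
    stop("all probes must have the same length")
  k <- length(probe)
  min_dist <- NA_integer_
  if (k > 1L) {
    d <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
      if (i < j) edit_distance(probe[i], probe[j]) else NA_integer_
    }))
    min_dist <- min(d, na.rm = TRUE)
    if (min_dist <= 2L * max_edits)
      warning(sprintf(
        "minimum pairwise probe edit distance %d is <= 2*max_edits (%d); %s",
        min_dist, 2L * max_edits,
        "reads may demultiplex ambiguously"))
  }
  structure(
    list(barcode_id = as.character(barcode_id), probe = probe,
         five_prime_primer = if (is.na(five_prime_primer)) NA_character_
                             else toupper(five_prime_primer),
         max_edits = as.integer(max_edits),
         min_pairwise_distance = min_dist),
    class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("probe_set: %d samples, probe length %d, max_edits %d\n",
              length(x$barcode_id), nchar(x$probe[1]), x$max_edits))
  if (!is.na(x$min_pairwise_distance))
    cat(sprintf("  min pairwise probe distance: %d\n",
                x$min_pairwise_distance))
  invisible(x)
}

#' Read a barcode table into a probe set
#'
#' Expects a headered TSV with columns `barcode_id` and `probe`; an
#' optional column `five_prime_primer` (same value on every row) supplies
#' the shared 5' cDNA primer.
#'
#' @param path TSV file path.
#' @param max_edits passed to [probe_set()].
#' @return a `probe_set`.
#' @export
read_barcode_table <- function(path, max_edits = 2L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("barcode_id", "probe") %in% names(tab)))
    stop("barcode table needs columns 'barcode_id' and 'probe': ", path)
  primer <- if ("five_prime_primer" %in% names(tab))
    tab$five_prime_primer[1] else NA_character_
  probe_set(tab$barcode_id, tab$probe, primer, max_edits = max_edits)
}
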