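#' Poly(A) tail acceptance criteria
#'
#' A terminal clipped segment is accepted as a poly(A) tail when all of
#' the following hold: (1) it is at least `min_len` nt long (default 15);
#' (2) it contains at least five consecutive adenosines; (3) non-A
#' residues make up less than half of it \emph{and} number fewer than 20.
#' `N` bases count as non-A.
#'
#' @param seq candidate tail sequence (read orientation).
#' @param min_len minimum clip length (default 15).
#' @param max_non_a maximum tolerated non-A count, exclusive (default 20).
#' @param max_non_a_frac maximum tolerated non-A fraction, exclusive
#'   (default 0.5).
#' @param min_a_run required run of consecutive A (default 5).
#' @return list with `ok` (logical), `reason` (`NA` if accepted, else the
#'   first failed criterion: `"short_clip"`, `"no_A5_run"`,
#'   `"too_many_nonA"`, `"high_nonA_fraction"`), and `counts` (named
#'   A/C/G/T/N integer vector).
#' @export
tail_criteria <- function(seq, min_len = 15L, max_non_a = 20L,
                          max_non_a_frac = 0.5, min_a_run = 5L) {
  counts <- base_counts(seq)
  len <- nchar(seq)
  non_a <- len - counts[["A"]]
  reason <- NA_character_
  if (len < min_len) {
    reason <- "short_clip"
  } else if (!grepl(strrep("A", min_a_run), seq, fixed = TRUE)) {
    reason <- "no_A5_run"
  } else if (non_a >= max_non_a) {
    reason <- "too_many_nonA"
  } else if (non_a / len >= max_non_a_frac) {
    reason <- "high_nonA_fraction"
  }
  list(ok = is.na(reason), reason = reason, counts = counts)
}

#' Extract the poly(A) tail from one genome alignment
#'
#' The tail of a transcript read appears as the clipped segment at the
#' read's 3' end: for a forward-strand alignment this is the clip at the
#' right of the stored sequence, for a reverse-strand alignment the clip
#' at the left (the aligner stores minus-strand reads
#' reverse-complemented). The clip is recovered from the clean read
#' sequence by length, so hard clips are handled identically to soft
#' clips. The segment is accepted per [tail_criteria()]. A read whose
#' 5'-end clip would itself pass all tail criteria is flagged suspicious
#' and rejected, so adapter remnants are never called as tails.
#'
#' @param aln one alignment record (a row of [read_alignments()] as a
#'   list or one-row data.frame).
#' @param clean_seq the oriented clean read sequence (5'->3', tail last).
#' @param num_passes pass count carried into the call (default 1).
#' @param ... criterion overrides passed to [tail_criteria()].
#' @return list with `ok`; on acceptance `tail_seq`, `tail_length`,
#'   `counts`; on rejection `reason` (`"nonprimary"`, `"unmapped"`,
#'   `"seq_length_mismatch"`, `"suspicious_5p_clip"`, or a
#'   [tail_criteria()] reason).
#' @export
extract_tail <- function(aln, clean_seq, num_passes = 1L, ...) {
  reject <- function(reason) list(ok = FALSE, reason = reason)
  if (isTRUE(aln$is_secondary) || isTRUE(aln$is_supplementary))
    return(reject("nonprimary"))
  if (isTRUE(aln$is_unmapped)) return(reject("unmapped"))

  ops <- cigar_ops(aln$cigar)
  qlen <- sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X", "H")])
  if (qlen != nchar(clean_seq)) return(reject("seq_length_mismatch"))

  clip_left <- leading_clip(ops)
  clip_right <- trailing_clip(ops)
  if (aln$ref_strand == "+") {
    clip3 <- clip_right; clip5 <- clip_left
  } else {
    clip3 <- clip_left; clip5 <- clip_right
  }
  n <- nchar(clean_seq)
  tail_seq <- if (clip3 > 0L) substr(clean_seq, n - clip3 + 1L, n) else ""
  crit <- tail_criteria(tail_seq, ...)
  if (!crit$ok) return(reject(crit$reason))

  if (clip5 > 0L) {
    head_seq <- substr(clean_seq, 1L, clip5)
    if (tail_criteria(head_seq, ...)$ok) return(reject("suspicious_5p_clip"))
  }

  list(ok = TRUE, tail_seq = tail_seq, tail_length = nchar(tail_seq),
       counts = crit$counts, num_passes = as.integer(num_passes))
}

cigar_ops <- function(cigar) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(len) != length(op)) stop("malformed CIGAR: ", cigar)
  list(op = op, len = len)
}

leading_clip <- function(ops) {
  i <- 1L; total <- 0L
  while (i <= length(ops$op) && ops$op[i] %in% c("S", "H")) {
    total <- total + ops$len[i]; i <- i + 1L
  }
  total
}

trailing_clip <- function(ops) {
  i <- length(ops$op); total <- 0L
  while (i >= 1L && ops$op[i] %in% c("S", "H")) {
    total <- total + ops$len[i]; i <- i - 1L
  }
  total
}

#' Call poly(A) tails for a whole alignment set
#'
#' Joins alignment records to clean reads by `read_id`, runs
#' [extract_tail()] on every primary alignment, and returns accepted
#' calls plus a rejection tally. Reads are pass-filtered first
#' (`min_passes`, default 10, the threshold used for accurate consensus
#' base calling).
#'
#' @param alignments table from [read_alignments()].
#' @param reads clean-read table (columns `read_id`, `sequence`,
#'   `num_passes`); typically one sample from [demux_reads()].
#' @param min_passes pass filter applied to the reads (default 10).
#' @param ... criterion overrides for [tail_criteria()].
#' @return list with `tails` (data.frame: `read_id`, `tail_seq`,
#'   `tail_length`, `A`, `C`, `G`, `T`, `N`, `num_passes`, `ref_name`,
#'   `ref_strand`, `end3` — strand-aware genomic cleavage coordinate) and
#'   `rejections` (data.frame: `read_id`, `reason`).
#' @export
call_tails <- function(alignments, reads, min_passes = 10L, ...) {
  reads <- filter_by_passes(reads, min_passes)
  keep <- alignments$read_id %in% reads$read_id
  alignments <- alignments[keep, , drop = FALSE]
  seq_of <- stats::setNames(reads$sequence, reads$read_id)
  np_of <- stats::setNames(reads$num_passes, reads$read_id)

  acc <- list(); rej <- list()
  for (i in seq_len(nrow(alignments))) {
    aln <- alignments[i, ]
    call <- extract_tail(as.list(aln), seq_of[[aln$read_id]],
                         np_of[[aln$read_id]], ...)
    if (call$ok) {
      acc[[length(acc) + 1L]] <- data.frame(
        read_id = aln$read_id, tail_seq = call$tail_seq,
        tail_length = call$tail_length,
        A = call$counts[["A"]], C = call$counts[["C"]],
        G = call$counts[["G"]], T = call$counts[["T"]],
        N = call$counts[["N"]], num_passes = call$num_passes,
        ref_name = aln$ref_name, ref_strand = aln$ref_strand,
        end3 = alignment_end3(aln), stringsAsFactors = FALSE)
    } else {
      rej[[length(rej) + 1L]] <- data.frame(
        read_id = aln$read_id, reason = call$reason,
        stringsAsFactors = FALSE)
    }
  }
  list(
    tails = if (length(acc)) do.call(rbind, acc) else data.frame(
      read_id = character(0), tail_seq = character(0),
      tail_length = integer(0), A = integer(0), C = integer(0),
      G = integer(0), T = integer(0), N = integer(0),
      num_passes = integer(0), ref_name = character(0),
      ref_strand = character(0), end3 = integer(0),
      stringsAsFactors = FALSE),
    rejections = if (length(rej)) do.call(rbind, rej) else data.frame(
      read_id = character(0), reason = character(0),
      stringsAsFactors = FALSE))
}

# Strand-aware genomic 3'-end (cleavage) coordinate of one alignment.
alignment_end3 <- function(aln) {
  ref_len <- GenomicAlignments::cigarWidthAlongReferenceSpace(aln$cigar)
  if (aln$ref_strand == "+") aln$pos + ref_len - 1L else aln$pos
}

#' Geometric mean of poly(A) tail lengths
#'
#' Per-gene tail lengths are lognormal-like, so gene-level tail length is
#' summarised by the geometric mean, `exp(mean(log(x)))`.
#'
#' @param lengths positive numeric vector.
#' @return the geometric mean.
#' @examples gene_geometric_mean(c(25, 100)) # 50
#' @export
gene_geometric_mean <- function(lengths) {
  if (length(lengths) == 0L) stop("empty length vector")
  if (any(lengths <= 0)) stop("tail lengths must be positive")
  exp(mean(log(lengths)))
}

#' Per-gene poly(A) tail summaries
#'
#' @param tails tail table carrying a `gene_id` column (see
#'   [assign_genes()]) plus `tail_length` and base counts.
#' @param min_reads minimum tails per gene (default 3); genes below it
#'   are omitted.
#' @return data.frame ordered by `gene_id`: `gene_id`, `n_reads`,
#'   `geo_mean_length`, `non_a_ratio` (pooled: total non-A bases over
#'   total tail bases).
#' @export
summarize_genes <- function(tails, min_reads = 3L) {
  stopifnot("gene_id" %in% names(tails))
  tails <- tails[!is.na(tails$gene_id), , drop = FALSE]
  split_idx <- split(seq_len(nrow(tails)), tails$gene_id)
  rows <- lapply(names(split_idx), function(g) {
    i <- split_idx[[g]]
    if (length(i) < min_reads) return(NULL)
    len <- tails$tail_length[i]
    data.frame(gene_id = g, n_reads = length(i),
               geo_mean_length = gene_geometric_mean(len),
               non_a_ratio = sum(len - tails$A[i]) / sum(len),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(data.frame(
    gene_id = character(0), n_reads = integer(0),
    geo_mean_length = numeric(0), non_a_ratio = numeric(0),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$gene_id), , drop = FALSE]
}

#' Tail length histogram
#'
#' Fixed-width binning of tail lengths with an optional long-tail view
#' restricted to tails above a threshold (by convention, 20-nt bins above
#' 200 nt). Bins are left-closed, right-open; the final bin absorbs the
#' maximum so counts always sum to the number of tails.
#'
#' @param lengths integer tail lengths.
#' @param binwidth bin width in nt (default 20).
#' @param min_length left edge of the first bin (default 0).
#' @return data.frame `bin_start`, `bin_end`, `count`.
#' @export
length_distribution <- function(lengths, binwidth = 20L, min_length = 0L) {
  if (length(lengths) == 0L)
    return(data.frame(bin_start = min_length,
                      bin_end = min_length + binwidth, count = 0L))
  top <- max(lengths, min_length + 1L)
  edges <- seq(min_length, top + binwidth, by = binwidth)
  idx <- findInterval(lengths, edges, rightmost.closed = FALSE)
  idx <- pmax(idx, 1L)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  data.frame(bin_start = edges[-length(edges)], bin_end = edges[-1L],
             count = counts)
}

#' Long-tail table
#'
#' Distribution of tails longer than `threshold` nt in `binwidth`-nt
#' bins, plus the overall fraction they represent.
#'
#' @param lengths integer tail lengths.
#' @param threshold lower cutoff, exclusive (default 200).
#' @param binwidth bin width (default 20).
#' @return list with `table` (binned counts starting at `threshold`) and
#'   `fraction` (share of all tails above the threshold).
#' @export
long_tail_table <- function(lengths, threshold = 200L, binwidth = 20L) {
  long <- lengths[lengths > threshold]
  list(table = length_distribution(long, binwidth, min_length = threshold),
       fraction = if (length(lengths)) length(long) / length(lengths)
                  else NA_real_)
}
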