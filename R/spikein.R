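#' Construct a spike-in design set
#'
#' Synthetic poly(A) spike-ins are barcoded cDNAs of a shared reporter
#' CDS with defined poly(A) tail lengths (10, 30, 50, 70, and 100 nt in
#' the canonical pool), used to calibrate tail-length measurement. Each
#' read has the layout 5' primer + barcode + reporter body + poly(A) +
#' 3' primer; the barcode sits before the start codon and identifies the
#' designed tail length.
#'
#' @param designs data.frame with columns `design_id`, `barcode`,
#'   `designed_tail` (positive integers; barcodes pairwise distinct).
#' @param body shared reporter CDS sequence.
#' @param five_prime_primer,three_prime_primer shared primer sequences.
#' @return object of class `spikein_design`.
#' @export
spikein_design <- function(designs, body, five_prime_primer,
                           three_prime_primer) {
  stopifnot(all(c("design_id", "barcode", "designed_tail")
                %in% names(designs)),
            all(designs$designed_tail > 0))
  if (anyDuplicated(designs$barcode))
    stop("spike-in barcodes must be pairwise distinct")
  structure(
    list(designs = data.frame(design_id = as.character(designs$design_id),
                              barcode = toupper(designs$barcode),
                              designed_tail = as.integer(designs$designed_tail),
                              stringsAsFactors = FALSE),
         body = toupper(body),
         five_prime_primer = toupper(five_prime_primer),
         three_prime_primer = toupper(three_prime_primer)),
    class = "spikein_design")
}

#' Built-in synthetic spike-in design
#'
#' A stand-in design pool shipped with the package (the real reporter
#' and primer sequences are proprietary to the original constructs):
#' five designs with tails of 10, 30, 50, 70, and 100 nt, 10-nt barcodes
#' at pairwise edit distance > 4, and a 600-nt synthetic reporter body.
#' Loaded from `inst/extdata/spikein_design_synthetic.tsv` and
#' `spikein_body_synthetic.fa`.
#'
#' @return a [spikein_design()].
#' @export
default_spikein_design <- function() {
  tsv <- system.file("extdata", "spikein_design_synthetic.tsv",
                     package = "ccstail", mustWork = TRUE)
  fa <- system.file("extdata", "spikein_body_synthetic.fa",
                    package = "ccstail", mustWork = TRUE)
  tab <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  seqs <- Biostrings::readDNAStringSet(fa)
  spikein_design(tab,
                 body = as.character(seqs[["body"]]),
                 five_prime_primer = as.character(seqs[["primer5"]]),
                 three_prime_primer = as.character(seqs[["primer3"]]))
}

#' Parse the structure of one spike-in read
#'
#' Orients the read (the reporter body may sit on either strand) and
#' locates, by edit-distance matching, the 5' primer, the barcode, the
#' reporter body boundaries (30-nt anchors at each end of the CDS), and
#' the 3' primer. The sequence between the reporter body and the 3'
#' primer is the measured poly(A) tail. Only full-length reads carrying
#' every feature in order are accepted; no minimum tail length is
#' imposed, so a 10-nt design is measurable.
#'
#' @param sequence read sequence.
#' @param design a [spikein_design()].
#' @param max_edits_primer edit tolerance for the primers (default 2).
#' @param max_edits_anchor edit tolerance for the 30-nt body anchors
#'   (default 3).
#' @param max_edits_barcode tolerance for barcode calling (default 2);
#'   the best design within tolerance wins, ties are rejected.
#' @return list with `ok`; on success `design_id`, `tail_seq`,
#'   `tail_length`, `non_a` (non-A bases in the tail); otherwise `reason`
#'   (`"no_body"`, `"no_5p_primer"`, `"no_3p_primer"`,
#'   `"bad_structure"`, `"barcode_unmatched"`, `"barcode_ambiguous"`).
#' @export
parse_spikein <- function(sequence, design, max_edits_primer = 2L,
                          max_edits_anchor = 3L, max_edits_barcode = 2L) {
  seq <- toupper(sequence)
  anchors <- spikein_anchors(design)
  ah <- find_probe(seq, anchors$tail, max_edits_anchor)
  if (nrow(ah) == 0L) return(list(ok = FALSE, reason = "no_body"))
  best <- ah[order(ah$edits, ah$start), , drop = FALSE][1, ]
  if (best$strand == "-") seq <- revcomp(seq)
  pats <- c(anchors$tail, anchors$head, design$five_prime_primer,
            design$three_prime_primer)
  tol <- c(max_edits_anchor, max_edits_anchor, max_edits_primer,
           max_edits_primer)
  hits <- lapply(seq_along(pats), function(i)
    find_probe(seq, pats[i], tol[i], both_strands = FALSE))
  parse_spikein_core(seq, hits[[1]], hits[[2]], hits[[3]], hits[[4]],
                     design, max_edits_barcode)
}

# Feature resolution on an oriented read, from precomputed forward-strand
# hit tables for the body-tail anchor (th), body-head anchor (hh), 5'
# primer (p5h) and 3' primer (p3h).
parse_spikein_core <- function(seq, th, hh, p5h, p3h, design,
                               max_edits_barcode) {
  fail <- function(reason) list(ok = FALSE, reason = reason)
  if (nrow(th) == 0L) return(fail("no_body"))
  body_end <- th$end[order(th$edits, th$start)][1]

  p5h <- p5h[p5h$end < body_end, , drop = FALSE]
  if (nrow(p5h) == 0L) return(fail("no_5p_primer"))
  o <- order(p5h$edits, p5h$start)
  p5_end <- p5h$end[o][1]

  hh <- hh[hh$start > p5_end & hh$end <= body_end, , drop = FALSE]
  if (nrow(hh) == 0L) return(fail("bad_structure"))
  o <- order(hh$edits, hh$start)
  body_start <- hh$start[o][1]

  p3h <- p3h[p3h$start > body_end, , drop = FALSE]
  if (nrow(p3h) == 0L) return(fail("no_3p_primer"))
  o <- order(p3h$edits, p3h$start)
  p3_start <- p3h$start[o][1]

  barcode_region <- substr(seq, p5_end + 1L, body_start - 1L)
  d <- vapply(design$designs$barcode, edit_distance,
              integer(1), b = barcode_region)
  if (!any(d <= max_edits_barcode)) return(fail("barcode_unmatched"))
  if (sum(d == min(d)) > 1L) return(fail("barcode_ambiguous"))
  design_id <- design$designs$design_id[which.min(d)]

  tail_seq <- if (p3_start - body_end > 1L)
    substr(seq, body_end + 1L, p3_start - 1L) else ""
  counts <- base_counts(tail_seq)
  list(ok = TRUE, design_id = design_id, tail_seq = tail_seq,
       tail_length = nchar(tail_seq),
       non_a = nchar(tail_seq) - counts[["A"]])
}

spikein_anchors <- function(design, anchor_len = 30L) {
  anchor_len <- min(anchor_len, nchar(design$body))
  list(tail = substr(design$body, nchar(design$body) - anchor_len + 1L,
                     nchar(design$body)),
       head = substr(design$body, 1L, anchor_len))
}

#' Parse a set of spike-in reads
#'
#' @param reads CCS read table (columns `read_id`, `sequence`).
#' @param design a [spikein_design()].
#' @inheritParams parse_spikein
#' @return list with `calls` (data.frame `read_id`, `design_id`,
#'   `tail_seq`, `tail_length`, `non_a`) and `not_full_length`
#'   (data.frame `read_id`, `reason`).
#' @export
parse_spikeins <- function(reads, design, max_edits_primer = 2L,
                           max_edits_anchor = 3L, max_edits_barcode = 2L) {
  n <- nrow(reads)
  seqs <- toupper(reads$sequence)
  anchors <- spikein_anchors(design)

  # batched orientation: flip reads whose best body-tail-anchor hit is
  # on the minus strand
  ori <- scan_probes(seqs, anchors$tail, max_edits_anchor)
  flip <- logical(n)
  if (nrow(ori)) {
    ori <- ori[order(ori$subject, ori$edits, ori$start), , drop = FALSE]
    first <- ori[!duplicated(ori$subject), , drop = FALSE]
    flip[first$subject] <- first$strand == "-"
  }
  seqs[flip] <- revcomp(seqs[flip])

  pats <- c(anchors$tail, anchors$head, design$five_prime_primer,
            design$three_prime_primer)
  tol <- c(max_edits_anchor, max_edits_anchor, max_edits_primer,
           max_edits_primer)
  hit_tab <- lapply(seq_along(pats), function(i) {
    h <- scan_probes(seqs, pats[i], tol[i], both_strands = FALSE)
    split(h[, c("start", "end", "strand", "edits")],
          factor(h$subject, levels = seq_len(n)))
  })
  no_hit <- empty_hits()

  acc <- list(); rej <- list()
  for (i in seq_len(n)) {
    r <- parse_spikein_core(
      seqs[i],
      hit_tab[[1]][[i]] %||% no_hit, hit_tab[[2]][[i]] %||% no_hit,
      hit_tab[[3]][[i]] %||% no_hit, hit_tab[[4]][[i]] %||% no_hit,
      design, max_edits_barcode)
    if (r$ok) {
      acc[[length(acc) + 1L]] <- data.frame(
        read_id = reads$read_id[i], design_id = r$design_id,
        tail_seq = r$tail_seq, tail_length = r$tail_length,
        non_a = r$non_a, stringsAsFactors = FALSE)
    } else {
      rej[[length(rej) + 1L]] <- data.frame(
        read_id = reads$read_id[i], reason = r$reason,
        stringsAsFactors = FALSE)
    }
  }
  list(
    calls = if (length(acc)) do.call(rbind, acc) else data.frame(
      read_id = character(0), design_id = character(0),
      tail_seq = character(0), tail_length = integer(0),
      non_a = integer(0), stringsAsFactors = FALSE),
    not_full_length = if (length(rej)) do.call(rbind, rej) else data.frame(
      read_id = character(0), reason = character(0),
      stringsAsFactors = FALSE))
}

#' Per-design spike-in calibration report
#'
#' Summarises parsed spike-in calls per design: number of full-length
#' reads, arithmetic mean measured tail length (each design has one
#' homogeneous designed length, so the arithmetic mean is the natural
#' estimator), recovery fraction (share of all full-length calls), and
#' the non-A mismatch rate (mismatching tail bases over total tail
#' bases) — the empirical upper bound on artifacts introduced after
#' reverse transcription.
#'
#' @param calls `calls` table from [parse_spikeins()].
#' @param design a [spikein_design()].
#' @return data.frame ordered as in the design: `design_id`,
#'   `designed_tail`, `n`, `mean_length` (`NA` when `n == 0`),
#'   `recovery_fraction`, `mismatch_rate`.
#' @export
spikein_report <- function(calls, design) {
  total <- nrow(calls)
  rows <- lapply(seq_len(nrow(design$designs)), function(i) {
    id <- design$designs$design_id[i]
    sub <- calls[calls$design_id == id, , drop = FALSE]
    n <- nrow(sub)
    data.frame(
      design_id = id,
      designed_tail = design$designs$designed_tail[i],
      n = n,
      mean_length = if (n > 0L) mean(sub$tail_length) else NA_real_,
      recovery_fraction = if (total > 0L) n / total else NA_real_,
      mismatch_rate = if (n > 0L && sum(sub$tail_length) > 0L)
        sum(sub$non_a) / sum(sub$tail_length) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
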