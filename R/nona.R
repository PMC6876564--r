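#' Per-transcript non-adenosine profile of a poly(A) tail
#'
#' Counts G, C, and U (read as T in consensus sequences) within one tail
#' and divides by tail length to give per-base ratios. `N` bases are
#' counted separately and excluded from the G/C/U tallies. The run
#' spectrum records maximal runs of each identical non-A base (a `GG`
#' directly followed by `C` contributes one G-run of 2 and one C-run of
#' 1).
#'
#' @param tail_seq tail sequence, read orientation (5'->3').
#' @return list with `counts` (named A/C/G/T/N), `ratios` (named G/C/U
#'   plus `non_a` = their sum), `runs` (data.frame `base`, `length`,
#'   `count` of maximal same-base non-A runs), and `tail_length`.
#' @examples
#' profile_tail("AAAGAAAATAAA")$ratios
#' @export
profile_tail <- function(tail_seq) {
  counts <- base_counts(tail_seq)
  len <- nchar(tail_seq)
  ratios <- c(G = counts[["G"]] / len, C = counts[["C"]] / len,
              U = counts[["T"]] / len)
  ratios <- c(ratios, non_a = sum(ratios))
  runs <- non_a_runs(tail_seq)
  list(counts = counts, ratios = ratios, runs = runs, tail_length = len)
}

# Maximal runs of identical non-A bases (G, C, T/U, N) with positions.
non_a_runs <- function(tail_seq) {
  b <- strsplit(toupper(tail_seq), "", fixed = TRUE)[[1]]
  r <- rle(b)
  stop_pos <- cumsum(r$lengths)
  start_pos <- stop_pos - r$lengths + 1L
  keep <- r$values != "A"
  data.frame(base = r$values[keep], length = r$lengths[keep],
             start = start_pos[keep], end = stop_pos[keep],
             stringsAsFactors = FALSE)
}

#' Run spectrum of non-A residues across many tails
#'
#' Counts of maximal non-A runs stratified by base (U, C, G) and run
#' length (1, 2, 3, 4+), the mono-/oligo-residue view of tail
#' modifications.
#'
#' @param tail_seqs character vector of tail sequences.
#' @return data.frame `base` (U/C/G), `run_length` (`"1"`, `"2"`, `"3"`,
#'   `"4+"`), `count`.
#' @export
run_spectrum <- function(tail_seqs) {
  runs <- do.call(rbind, lapply(tail_seqs, non_a_runs))
  grid <- expand.grid(base = c("U", "C", "G"),
                      run_length = c("1", "2", "3", "4+"),
                      stringsAsFactors = FALSE)
  grid$count <- 0L
  if (!is.null(runs) && nrow(runs)) {
    runs <- runs[runs$base %in% c("T", "C", "G"), , drop = FALSE]
    runs$base[runs$base == "T"] <- "U"
    runs$cat <- ifelse(runs$length >= 4L, "4+", as.character(runs$length))
    tab <- table(runs$base, runs$cat)
    for (i in seq_len(nrow(grid))) {
      b <- grid$base[i]; l <- grid$run_length[i]
      if (b %in% rownames(tab) && l %in% colnames(tab))
        grid$count[i] <- as.integer(tab[b, l])
    }
  }
  grid
}

#' Pooled non-A ratio of a gene
#'
#' Gene-level non-A ratio is computed the same way as for a transcript,
#' pooling all transcripts of the gene: total non-A bases divided by
#' total tail bases (not the mean of per-transcript ratios).
#'
#' @param tail_seqs tails of one gene.
#' @return a single ratio in `[0, 1]`.
#' @export
gene_non_a_ratio <- function(tail_seqs) {
  counts <- Reduce(`+`, lapply(tail_seqs, base_counts))
  total <- sum(counts)
  if (total == 0L) stop("no tail bases")
  (total - counts[["A"]]) / total
}

#' Fraction of reads with internal non-A residues
#'
#' Two variants are reported: `raw` counts a read as modified if any
#' non-A base occurs anywhere in the tail; `internal` first strips the
#' maximal terminal (3') non-A run — terminal residues are partially lost
#' to adapter pairing during library construction, so they are the less
#' reliable signal — and then tests the remainder. A per-length-bin table
#' accompanies the global fractions.
#'
#' @param tail_seqs character vector of tail sequences.
#' @param binwidth tail-length bin width for the binned table (default
#'   20 nt).
#' @return list with `raw`, `internal` (global fractions) and `by_length`
#'   (data.frame `bin_start`, `bin_end`, `n`, `frac_raw`,
#'   `frac_internal`, `base_freq_non_a` — per-base non-A frequency in the
#'   bin).
#' @export
fraction_with_internal_non_a <- function(tail_seqs, binwidth = 20L) {
  n <- length(tail_seqs)
  if (n == 0L)
    return(list(raw = NA_real_, internal = NA_real_,
                by_length = data.frame()))
  stripped <- sub("[^A]+$", "", tail_seqs)
  has_raw <- grepl("[^A]", tail_seqs)
  has_int <- grepl("[^A]", stripped)
  len <- nchar(tail_seqs)
  non_a <- len - vapply(tail_seqs,
                        function(s) base_counts(s)[["A"]], integer(1))

  bin <- (len %/% binwidth) * binwidth
  by <- lapply(sort(unique(bin)), function(b) {
    i <- bin == b
    data.frame(bin_start = b, bin_end = b + binwidth, n = sum(i),
               frac_raw = mean(has_raw[i]),
               frac_internal = mean(has_int[i]),
               base_freq_non_a = sum(non_a[i]) / sum(len[i]))
  })
  list(raw = mean(has_raw), internal = mean(has_int),
       by_length = do.call(rbind, by))
}

#' Positional profile of non-A residues along tails
#'
#' Tails vary in length, so each non-A base is placed into one of `k`
#' equal relative-position bins (bin 1 = 5'-most). An absolute 5'-anchored
#' profile over the first `abs_max` nt is emitted alongside.
#'
#' @param tail_seqs character vector of tails.
#' @param k number of relative bins (default 20).
#' @param abs_max length of the absolute profile (default 100 nt).
#' @return list of two data.frames: `relative` (`bin`, per-base counts
#'   `U`, `C`, `G`, `total`, and `frequency` = total non-A per base
#'   sampled in that bin) and `absolute` (`position`, `U`, `C`, `G`,
#'   `coverage`).
#' @export
positional_profile <- function(tail_seqs, k = 20L, abs_max = 100L) {
  rel <- data.frame(bin = seq_len(k), U = 0L, C = 0L, G = 0L,
                    total = 0L, sampled = 0L)
  abs <- data.frame(position = seq_len(abs_max), U = 0L, C = 0L, G = 0L,
                    coverage = 0L)
  for (s in tail_seqs) {
    b <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    len <- length(b)
    if (len == 0L) next
    pos <- seq_len(len)
    bins <- pmin(ceiling(pos / len * k), k)
    rel$sampled <- rel$sampled + tabulate(bins, nbins = k)
    for (base in c("T", "C", "G")) {
      col <- if (base == "T") "U" else base
      hit <- bins[b == base]
      if (length(hit))
        rel[[col]] <- rel[[col]] + tabulate(hit, nbins = k)
      apos <- pos[b == base & pos <= abs_max]
      if (length(apos))
        abs[[col]] <- abs[[col]] + tabulate(apos, nbins = abs_max)
    }
    cov <- min(len, abs_max)
    abs$coverage[seq_len(cov)] <- abs$coverage[seq_len(cov)] + 1L
  }
  rel$total <- rel$U + rel$C + rel$G
  rel$frequency <- ifelse(rel$sampled > 0, rel$total / rel$sampled, NA)
  list(relative = rel[, c("bin", "U", "C", "G", "total", "sampled",
                          "frequency")],
       absolute = abs)
}

#' Classify the anchoring site of an oligo(dT)-T30VN RT primer
#'
#' Conventional full-length cDNA libraries prime reverse transcription
#' with an oligo(dT) primer whose terminal VN bases normally anchor at
#' the 3'-UTR / poly(A) junction (model `a`), discarding the tail. If the
#' tail body contains non-A residues, the VN end can instead base-pair
#' within the tail (model `b`), leaving a stretch of genuine tail
#' sequence — at least one A, then the 1-2 anchoring non-A base(s) —
#' between the 3'-UTR end and the long terminal A-stretch that is the
#' primer's T30 complement.
#'
#' @param sequence oriented read sequence (5'->3', adapter trimmed).
#' @param utr_end 1-based position of the last 3'-UTR base in the read.
#' @param min_terminal_a_run minimum length of the terminal A-run taken
#'   as the T30 complement (default 25 nt).
#' @return list with `model` (`"a"`, `"b"`, or `"not_classifiable"`),
#'   and for model `b` `n_anchor_non_a` (1 or 2) and `anchor_bases`; a
#'   `reason` accompanies non-classifiable calls (`"no_terminal_a_run"`
#'   or `"complex_junction"`).
#' @export
classify_vn_anchor <- function(sequence, utr_end,
                               min_terminal_a_run = 25L) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  stopifnot(utr_end >= 0L, utr_end <= n)
  m <- regexpr(sprintf("A{%d,}$", min_terminal_a_run), sequence)
  if (m == -1L)
    return(list(model = "not_classifiable",
                reason = "no_terminal_a_run"))
  run_start <- as.integer(m)
  if (run_start <= utr_end + 1L)
    return(list(model = "a", n_anchor_non_a = 0L,
                anchor_bases = ""))
  middle <- substr(sequence, utr_end + 1L, run_start - 1L)
  if (grepl("^A+[^A]{1,2}$", middle)) {
    anchor <- sub("^A+", "", middle)
    return(list(model = "b", n_anchor_non_a = nchar(anchor),
                anchor_bases = anchor))
  }
  list(model = "not_classifiable", reason = "complex_junction")
}

#' Summarise VN-anchoring calls over a read set
#'
#' @param sequences oriented, adapter-trimmed read sequences.
#' @param utr_ends matching vector of 3'-UTR end positions.
#' @param ... passed to [classify_vn_anchor()].
#' @return list with `calls` (per-read data.frame: `model`,
#'   `n_anchor_non_a`, `anchor_bases`, `reason`), `percent_model_b`
#'   (share of model-b calls among classifiable reads, in percent), and
#'   `anchor_table` (counts by anchor base combination).
#' @export
vn_anchor_summary <- function(sequences, utr_ends, ...) {
  stopifnot(length(sequences) == length(utr_ends))
  calls <- lapply(seq_along(sequences), function(i) {
    r <- classify_vn_anchor(sequences[i], utr_ends[i], ...)
    data.frame(model = r$model,
               n_anchor_non_a = r$n_anchor_non_a %||% NA_integer_,
               anchor_bases = r$anchor_bases %||% NA_character_,
               reason = r$reason %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  classifiable <- calls$model %in% c("a", "b")
  pct_b <- if (any(classifiable))
    100 * mean(calls$model[classifiable] == "b") else NA_real_
  bt <- table(calls$anchor_bases[calls$model == "b"])
  anchor_table <- data.frame(anchor_bases = names(bt),
                             count = as.integer(bt),
                             stringsAsFactors = FALSE)
  list(calls = calls, percent_model_b = pct_b,
       anchor_table = anchor_table)
}
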