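#' Demultiplex, orient, and trim one CCS read
#'
#' Implements the read-cleaning procedure for barcoded full-length cDNA
#' CCS reads:
#' \enumerate{
#'   \item every sample probe is searched on both strands at
#'     `probes$max_edits`; hits to two or more distinct barcodes make the
#'     read \emph{ambiguous} (discarded), no hit leaves it
#'     \emph{unassigned};
#'   \item the read is oriented 5' to 3' with the poly(A) tail at the 3'
#'     end, i.e. so that the reverse complement of the matched probe lies
#'     at the 3' side (a read whose probe matches on the forward strand
#'     is reverse-complemented);
#'   \item the 3' adapter is trimmed: the retained sequence ends where
#'     the 3'-most probe match begins;
#'   \item concatemers are resolved by keeping the 3'-most unit: any
#'     interior probe match (or interior 5'-primer match) and all
#'     sequence 5' of it are dropped, repeatedly;
#'   \item the 5' cDNA primer is removed when present near the read
#'     start (searched within the first `primer_window` nt).
#' }
#'
#' @param read one-row CCS read (list or data.frame row with `read_id`,
#'   `sequence`, `num_passes`).
#' @param probes a [probe_set()].
#' @param min_len minimum retained sequence length (default 50 nt);
#'   shorter results are unassigned with reason `"too_short"`.
#' @param primer_window how far from the 5' end the cDNA primer may start
#'   (default 50 nt).
#' @return a list with `status` (`"clean"`, `"ambiguous"`,
#'   `"unassigned"`), and for clean reads `barcode_id`, `sequence`
#'   (oriented, trimmed), `num_passes`, `trim_log` (data.frame of
#'   `event`, `start`, `end`); unassigned results carry `reason` (one of
#'   `"no_probe"`, `"orientation_conflict"`, `"too_short"`).
#' @export
clean_read <- function(read, probes, min_len = 50L, primer_window = 50L) {
  hits <- scan_probes(read$sequence, probes$probe, probes$max_edits)
  clean_read_core(read, probes, hits, min_len, primer_window)
}

# Core cleaner taking precomputed step-1 hits (columns pattern, start,
# end, strand, edits) so batch demultiplexing can scan all reads at once.
clean_read_core <- function(read, probes, hits, min_len, primer_window) {
  seq <- toupper(read$sequence)
  out <- list(read_id = read$read_id, status = "unassigned",
              reason = "no_probe", barcode_id = NA_character_,
              sequence = NA_character_,
              num_passes = read$num_passes %||% 1L,
              trim_log = empty_trim_log())
  if (nrow(hits) == 0L) return(out)

  barcodes_hit <- unique(probes$barcode_id[hits$pattern])
  if (length(barcodes_hit) >= 2L) {
    out$status <- "ambiguous"
    out$reason <- "multiple_barcodes"
    return(out)
  }
  bc_idx <- match(barcodes_hit, probes$barcode_id)
  probe <- probes$probe[bc_idx]
  out$barcode_id <- barcodes_hit

  strands <- unique(hits$strand)
  if (length(strands) == 2L) {
    out$reason <- "orientation_conflict"
    return(out)
  }

  log <- empty_trim_log()
  # Oriented reads carry RC(probe) at the 3' end, i.e. minus-strand probe
  # hits. A forward-strand match means the read is stored tail-first.
  if (strands == "+") {
    n <- nchar(seq)
    seq <- revcomp(seq)
    log <- add_trim_event(log, "oriented_rc", 1L, n)
    hits <- data.frame(start = n - hits$end + 1L, end = n - hits$start + 1L,
                       strand = "-", edits = hits$edits,
                       stringsAsFactors = FALSE)
  }

  # 3' adapter trim at the 3'-most probe match.
  cut <- max(hits$start)
  log <- add_trim_event(log, "adapter_trim", cut, nchar(seq))
  seq <- substr(seq, 1L, cut - 1L)

  # Concatemer resolution: keep the 3'-most unit. Interior probe hits
  # (either strand) or interior 5'-primer hits mark unit boundaries; the
  # boundary match and everything 5' of it are dropped.
  repeat {
    boundary <- 0L
    if (nchar(seq) >= nchar(probe)) {
      ih <- find_probe(seq, probe, probes$max_edits)
      if (nrow(ih) > 0L) boundary <- max(ih$end)
    }
    if (boundary == 0L && !is.na(probes$five_prime_primer) &&
        nchar(seq) >= nchar(probes$five_prime_primer)) {
      ph <- find_probe(seq, probes$five_prime_primer, probes$max_edits,
                       both_strands = FALSE)
      ph <- ph[ph$start > primer_window, , drop = FALSE]
      if (nrow(ph) > 0L) boundary <- max(ph$end)
    }
    if (boundary == 0L) break
    log <- add_trim_event(log, "concatemer_trim", 1L, boundary)
    seq <- substr(seq, boundary + 1L, nchar(seq))
  }

  # 5' cDNA primer removal, tolerated when absent.
  if (!is.na(probes$five_prime_primer)) {
    plen <- nchar(probes$five_prime_primer)
    window <- substr(seq, 1L, primer_window + plen)
    ph <- find_probe(window, probes$five_prime_primer, probes$max_edits,
                     both_strands = FALSE)
    ph <- ph[ph$start <= primer_window, , drop = FALSE]
    if (nrow(ph) > 0L) {
      cut5 <- ph$end[which.min(ph$start)]
      log <- add_trim_event(log, "primer5_trim", 1L, cut5)
      seq <- substr(seq, cut5 + 1L, nchar(seq))
    }
  }

  if (nchar(seq) < min_len) {
    out$reason <- "too_short"
    return(out)
  }
  out$status <- "clean"
  out$reason <- NA_character_
  out$sequence <- seq
  out$trim_log <- log
  out
}

empty_trim_log <- function() {
  data.frame(event = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

add_trim_event <- function(log, event, start, end) {
  rbind(log, data.frame(event = event, start = as.integer(start),
                        end = as.integer(end), stringsAsFactors = FALSE))
}

#' Demultiplex a set of CCS reads
#'
#' Batch wrapper around [clean_read()]: the initial probe scan is done
#' for all reads in one pass, then each read is oriented, trimmed, and
#' assigned.
#'
#' @param reads CCS read table ([read_ccs()]).
#' @param probes a [probe_set()].
#' @inheritParams clean_read
#' @return a list with `clean` (data.frame: `read_id`, `barcode_id`,
#'   `sequence`, `num_passes`, `n_trim_events`), `report` (per-category
#'   counts: assigned per sample, ambiguous, unassigned by reason,
#'   concatemer count), and `details` (per-read status table).
#' @export
demux_reads <- function(reads, probes, min_len = 50L, primer_window = 50L) {
  stopifnot(nrow(reads) >= 0L)
  all_hits <- if (nrow(reads) > 0L)
    scan_probes(reads$sequence, probes$probe, probes$max_edits)
  else data.frame(subject = integer(0), pattern = integer(0))
  hit_split <- split(seq_len(nrow(all_hits)), all_hits$subject)

  res <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    idx <- hit_split[[as.character(i)]]
    hits <- if (is.null(idx)) empty_hits()
            else all_hits[idx, c("pattern", "start", "end", "strand",
                                 "edits"), drop = FALSE]
    res[[i]] <- clean_read_core(
      list(read_id = reads$read_id[i], sequence = reads$sequence[i],
           num_passes = reads$num_passes[i]),
      probes, hits, min_len, primer_window)
  }

  status <- vapply(res, `[[`, character(1), "status")
  reason <- vapply(res, function(r) r$reason %||% NA_character_,
                   character(1))
  barcode <- vapply(res, `[[`, character(1), "barcode_id")
  n_concat <- vapply(res, function(r) {
    sum(r$trim_log$event == "concatemer_trim")
  }, integer(1))

  is_clean <- status == "clean"
  clean <- data.frame(
    read_id = vapply(res[is_clean], `[[`, character(1), "read_id"),
    barcode_id = barcode[is_clean],
    sequence = vapply(res[is_clean], `[[`, character(1), "sequence"),
    num_passes = vapply(res[is_clean], `[[`, integer(1), "num_passes"),
    n_trim_events = vapply(res[is_clean], function(r) nrow(r$trim_log),
                           integer(1)),
    stringsAsFactors = FALSE)

  details <- data.frame(read_id = reads$read_id, status = status,
                        reason = reason, barcode_id = barcode,
                        n_concatemer_trims = n_concat,
                        stringsAsFactors = FALSE)

  per_sample <- table(factor(barcode[is_clean],
                             levels = probes$barcode_id))
  report <- data.frame(
    category = c(paste0("assigned:", probes$barcode_id),
                 "ambiguous", "unassigned:no_probe",
                 "unassigned:orientation_conflict",
                 "unassigned:too_short", "reads_with_concatemer_trims"),
    count = c(as.integer(per_sample),
              sum(status == "ambiguous"),
              sum(status == "unassigned" & reason == "no_probe"),
              sum(status == "unassigned" & reason == "orientation_conflict"),
              sum(status == "unassigned" & reason == "too_short"),
              sum(n_concat > 0L)),
    stringsAsFactors = FALSE)

  list(clean = clean, report = report, details = details)
}

#' Write demultiplexing outputs
#'
#' One FASTQ per sample (clean, oriented, trimmed reads with `np=K` pass
#' tokens) plus a TSV report of assignment counts.
#'
#' @param demux result of [demux_reads()].
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_demux <- function(demux, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (bc in unique(demux$clean$barcode_id)) {
    sub <- demux$clean[demux$clean$barcode_id == bc, , drop = FALSE]
    p <- file.path(dir, paste0(bc, ".clean.fastq"))
    write_ccs(sub, p, format = "fastq")
    paths[bc] <- p
  }
  rp <- file.path(dir, "demux_report.tsv")
  utils::write.table(demux$report, rp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["report"] <- rp
  invisible(paths)
}
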