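#' Read CCS reads from FASTA, FASTQ, or unaligned BAM
#'
#' Normalises circular consensus reads to a single table. The number of
#' sequencing passes is taken from the PacBio `np` BAM tag (uBAM input)
#' or from an `np=K` token in the FASTA/FASTQ description line; records
#' without pass information get `num_passes = 1` and a warning is raised
#' once per file. Records with empty sequences are skipped and counted.
#'
#' @param path input file.
#' @param format one of `"auto"`, `"fasta"`, `"fastq"`, `"ubam"`. `"auto"`
#'   dispatches on the file extension (`.fa/.fasta`, `.fq/.fastq`,
#'   `.bam/.ubam`).
#' @return data.frame with columns `read_id`, `sequence`, `num_passes`,
#'   `source`; attribute `skipped` counts malformed (empty-sequence)
#'   records.
#' @export
read_ccs <- function(path, format = c("auto", "fasta", "fastq", "ubam")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read CCS input: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      fa = , fasta = , fna = "fasta",
      fq = , fastq = "fastq",
      bam = , ubam = "ubam",
      stop("cannot infer format from extension '", ext,
           "'; pass format= explicitly"))
  }

  if (format == "ubam") {
    param <- Rsamtools::ScanBamParam(what = c("qname", "seq"), tag = "np")
    rec <- Rsamtools::scanBam(path, param = param)[[1]]
    ids <- rec$qname
    seqs <- as.character(rec$seq)
    np <- rec$tag$np
    if (is.null(np)) np <- rep(NA_integer_, length(ids))
  } else {
    set <- Biostrings::readDNAStringSet(path, format = format)
    desc <- names(set)
    ids <- sub("\\s.*$", "", desc)
    seqs <- as.character(set)
    np <- parse_np_token(desc)
  }

  keep <- nzchar(seqs)
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    warning(n_skipped, " empty-sequence record(s) skipped in ", path)
  ids <- ids[keep]; seqs <- seqs[keep]; np <- np[keep]

  if (anyDuplicated(ids))
    stop("duplicate read_id values in ", path)
  if (anyNA(np)) {
    warning(sum(is.na(np)), " read(s) without pass information in ",
            basename(path), "; num_passes set to 1")
    np[is.na(np)] <- 1L
  }
  if (any(np < 1L)) stop("num_passes must be >= 1")

  df <- data.frame(read_id = ids, sequence = toupper(seqs),
                   num_passes = as.integer(np),
                   source = rep_len(format, length(ids)),
                   stringsAsFactors = FALSE)
  attr(df, "skipped") <- n_skipped
  df
}

# np=K token anywhere in the description line -> integer, else NA.
parse_np_token <- function(desc) {
  out <- rep(NA_integer_, length(desc))
  has <- grepl("np=[0-9]+", desc)
  out[has] <- as.integer(sub(".*?np=([0-9]+).*", "\\1", desc[has]))
  out
}

#' Write CCS reads to FASTA or FASTQ
#'
#' The pass count is carried as an `np=K` token in the description line,
#' so `write_ccs()` then [read_ccs()] round-trips `read_id`, `sequence`
#' and `num_passes` losslessly. FASTQ qualities are constant placeholders
#' (consensus reads have no meaningful per-base qualities here).
#'
#' @param reads data.frame as returned by [read_ccs()].
#' @param path output file.
#' @param format `"fastq"` (default) or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_ccs <- function(reads, path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  set <- Biostrings::DNAStringSet(reads$sequence)
  names(set) <- sprintf("%s np=%d", reads$read_id, reads$num_passes)
  Biostrings::writeXStringSet(set, path, format = format)
  invisible(path)
}

#' Filter CCS reads by pass count
#'
#' Consensus accuracy grows with the number of passes; downstream tail
#' and composition calling uses reads with at least 10 passes by default.
#'
#' @param reads CCS read table.
#' @param min_passes minimum number of passes (default 10).
#' @return the subset with `num_passes >= min_passes`, order preserved.
#' @export
filter_by_passes <- function(reads, min_passes = 10L) {
  stopifnot(min_passes >= 1L)
  reads[reads$num_passes >= min_passes, , drop = FALSE]
}

#' Read genome alignments from SAM or BAM
#'
#' Normalises alignment records to a flat table. SAM text input is
#' converted in place via [Rsamtools::asBam()]; BAM is read directly.
#' Secondary (0x100) and supplementary (0x800) records are flagged, never
#' silently used downstream.
#'
#' @param path `.sam` or `.bam` file.
#' @return data.frame with columns `read_id`, `flag`, `ref_name`, `pos`
#'   (1-based leftmost), `cigar`, `ref_strand` (`"+"`/`"-"`),
#'   `seq_stored` (aligner orientation), `is_secondary`,
#'   `is_supplementary`, `is_unmapped`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("cannot read alignments: ", path)
  bam <- path
  if (tolower(tools::file_ext(path)) == "sam") {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- rec$flag
  data.frame(
    read_id = rec$qname,
    flag = flag,
    ref_name = as.character(rec$rname),
    pos = rec$pos,
    cigar = rec$cigar,
    ref_strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    seq_stored = as.character(rec$seq),
    is_secondary = bitwAnd(flag, 256L) > 0L,
    is_supplementary = bitwAnd(flag, 2048L) > 0L,
    is_unmapped = bitwAnd(flag, 4L) > 0L,
    stringsAsFactors = FALSE)
}
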