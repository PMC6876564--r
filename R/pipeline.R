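#' Run the full tail-analysis pipeline
#'
#' Orchestrates demultiplexing, tail calling from a supplied alignment
#' file, non-A profiling, gene assignment, and polyadenylation-site
#' clustering, writing one TSV per stage plus a run manifest. Alignment
#' is an explicit external step: the pipeline consumes a SAM/BAM of the
#' clean reads produced by a splice-aware long-read aligner run with
#' secondary alignments suppressed (e.g. `minimap2 -ax splice -uf
#' --secondary=no`), and never shells out to one itself.
#'
#' @param reads path to the CCS reads (FASTA/FASTQ/uBAM).
#' @param barcodes path to the barcode TSV (see [read_barcode_table()]).
#' @param alignments path to SAM/BAM of clean reads against the genome.
#' @param gtf path to the gene annotation.
#' @param out_dir output directory.
#' @param min_passes pass filter for tail and composition calling
#'   (default 10).
#' @param min_reads minimum tails per gene for summaries (default 3).
#' @param window,min_support polyadenylation-site clustering parameters.
#' @param ref_bed optional reference poly(A)-site BED for overlap
#'   statistics.
#' @param max_edits demultiplexing edit tolerance (default 2).
#' @param min_len minimum retained read length after trimming.
#' @return the run manifest: per-stage record counts, parameters,
#'   warnings, and output paths; stage tables are also returned in
#'   `$tables`.
#' @export
run_pipeline <- function(reads, barcodes, alignments, gtf, out_dir,
                         min_passes = 10L, min_reads = 3L, window = 24L,
                         min_support = 2L, ref_bed = NULL,
                         max_edits = 2L, min_len = 50L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings <- character(0)
  note <- function(...) warnings <<- c(warnings, sprintf(...))

  ccs <- read_ccs(reads)
  probes <- read_barcode_table(barcodes, max_edits = max_edits)
  demux <- demux_reads(ccs, probes, min_len = min_len)
  write_demux(demux, file.path(out_dir, "demux"))

  aln <- read_alignments(alignments)
  index <- build_exon_index(gtf)
  assign <- assign_genes(aln, index)
  gene_of <- stats::setNames(assign$gene_id, assign$read_id)

  tables <- list(demux_report = demux$report)
  all_tails <- list()
  for (bc in probes$barcode_id) {
    clean <- demux$clean[demux$clean$barcode_id == bc, , drop = FALSE]
    if (nrow(clean) == 0L) {
      note("sample %s: no clean reads", bc)
      next
    }
    called <- call_tails(aln, clean, min_passes = min_passes)
    tails <- called$tails
    tails$gene_id <- unname(gene_of[tails$read_id])
    tails$sample <- bc
    all_tails[[bc]] <- tails
    utils::write.table(
      tails, file.path(out_dir, paste0(bc, ".tails.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)

    summary <- summarize_genes(tails, min_reads = min_reads)
    tables[[paste0(bc, ".genes")]] <- summary
    utils::write.table(
      summary, file.path(out_dir, paste0(bc, ".genes.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  tails_all <- do.call(rbind, all_tails)
  if (!is.null(tails_all) && nrow(tails_all)) {
    sites <- call_polya_sites(tails_all, window = window,
                              min_support = min_support)
    apa <- classify_apa_genes(sites)
    tables$polya_sites <- sites
    tables$apa_classes <- apa
    utils::write.table(sites, file.path(out_dir, "polya_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(apa, file.path(out_dir, "apa_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ref_bed)) {
      sites$ref_name <- tails_all$ref_name[1]
      cmp <- compare_sites_to_reference(sites, ref_bed)
      tables$reference_overlap <- data.frame(
        fraction_overlapping = cmp$fraction_overlapping)
    }

    spectrum <- run_spectrum(tails_all$tail_seq)
    tables$run_spectrum <- spectrum
    utils::write.table(spectrum, file.path(out_dir, "run_spectrum.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    prof <- positional_profile(tails_all$tail_seq)
    utils::write.table(prof$relative,
                       file.path(out_dir, "positional_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tables$positional_profile <- prof$relative
  }

  manifest <- list(
    tool = paste0("ccstail ", as.character(utils::packageVersion("ccstail"))),
    parameters = list(min_passes = min_passes, min_reads = min_reads,
                      window = window, min_support = min_support,
                      max_edits = max_edits, min_len = min_len),
    counts = list(
      input_reads = nrow(ccs),
      clean_reads = nrow(demux$clean),
      ambiguous = sum(demux$details$status == "ambiguous"),
      unassigned = sum(demux$details$status == "unassigned"),
      alignments = nrow(aln),
      tails = if (is.null(tails_all)) 0L else nrow(tails_all)),
    warnings = warnings,
    out_dir = out_dir,
    tables = tables)
  class(manifest) <- "ccstail_manifest"
  manifest
}

#' @export
print.ccstail_manifest <- function(x, ...) {
  cat(x$tool, "\n")
  for (k in names(x$counts))
    cat(sprintf("  %-14s %d\n", k, x$counts[[k]]))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Summary report across replicates
#'
#' Builds the standard result tables from per-sample tail calls: global
#' tail-length histograms per replicate, the long-tail (>200 nt) table,
#' per-replicate non-A read fractions, and pairwise between-replicate
#' correlations of per-gene tail length (genes summarised by geometric
#' mean; correlation over genes passing `min_reads` in both replicates).
#' With a single gene in common the correlation is undefined and
#' reported as `NA`.
#'
#' @param tails_by_sample named list of tail tables (with `gene_id`).
#' @param min_reads per-gene read floor for the correlation analysis
#'   (default 10).
#' @param binwidth histogram bin width (default 20 nt).
#' @return list with `histograms`, `long_tails`, `non_a`, and
#'   `correlations` (data.frame `sample_a`, `sample_b`, `n_genes`,
#'   `pearson`, `spearman`).
#' @export
make_report <- function(tails_by_sample, min_reads = 10L, binwidth = 20L) {
  stopifnot(is.list(tails_by_sample), length(tails_by_sample) >= 1L)
  histograms <- lapply(tails_by_sample, function(t)
    length_distribution(t$tail_length, binwidth))
  long_tails <- lapply(tails_by_sample, function(t)
    long_tail_table(t$tail_length))
  non_a <- vapply(tails_by_sample, function(t)
    fraction_with_internal_non_a(t$tail_seq)$internal, numeric(1))

  summaries <- lapply(tails_by_sample, summarize_genes,
                      min_reads = min_reads)
  ids <- names(tails_by_sample)
  pairs <- if (length(ids) >= 2L) utils::combn(ids, 2L, simplify = FALSE)
           else list()
  correlations <- do.call(rbind, lapply(pairs, function(p) {
    a <- summaries[[p[1]]]; b <- summaries[[p[2]]]
    shared <- intersect(a$gene_id, b$gene_id)
    x <- a$geo_mean_length[match(shared, a$gene_id)]
    y <- b$geo_mean_length[match(shared, b$gene_id)]
    enough <- length(shared) >= 2L && stats::sd(x) > 0 && stats::sd(y) > 0
    data.frame(
      sample_a = p[1], sample_b = p[2], n_genes = length(shared),
      pearson = if (enough) stats::cor(x, y) else NA_real_,
      spearman = if (enough) stats::cor(x, y, method = "spearman")
                 else NA_real_,
      stringsAsFactors = FALSE)
  }))
  list(histograms = histograms, long_tails = long_tails, non_a = non_a,
       correlations = correlations %||% data.frame())
}
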