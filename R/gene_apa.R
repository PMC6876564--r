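#' Build a merged-exon gene index from a GTF/GFF annotation
#'
#' Exon records are grouped by `gene_id`; duplicated exons collapse and
#' overlapping exons are merged, so each gene is a set of disjoint
#' intervals. GTF's 1-based inclusive coordinates are carried as
#' `GRanges` and converted to 0-based half-open only at external
#' boundaries.
#'
#' @param gtf path to a GTF/GFF file with `type == "exon"` features
#'   carrying `gene_id`.
#' @return object of class `exon_index`: list with `exons` (a
#'   `GRangesList`, one reduced element per gene) and `strand` (named
#'   character vector per gene).
#' @export
build_exon_index <- function(gtf) {
  gr <- rtracklayer::import(gtf)
  gr <- gr[gr$type == "exon"]
  has_gene <- !is.na(gr$gene_id) & nzchar(gr$gene_id)
  if (any(!has_gene)) {
    warning(sum(!has_gene), " exon record(s) without gene_id skipped")
    gr <- gr[has_gene]
  }
  by_gene <- GenomicRanges::reduce(
    GenomicRanges::split(gr, gr$gene_id))
  strand <- vapply(as.list(by_gene), function(g) {
    as.character(GenomicRanges::strand(g)[1])
  }, character(1))
  structure(list(exons = by_gene, strand = strand), class = "exon_index")
}

#' @export
print.exon_index <- function(x, ...) {
  cat(sprintf("exon_index: %d genes, %d merged exon intervals\n",
              length(x$exons), sum(lengths(x$exons))))
  invisible(x)
}

#' Assign alignments to genes by exon overlap
#'
#' Aligned blocks (reference-consuming CIGAR runs M/=/X/D; introns N are
#' excluded) are intersected with the merged exon intervals. An
#' alignment overlapping exactly one gene by at least one base is
#' assigned to it; overlap with two or more genes discards the read
#' (`"discarded_multi"`); no overlap yields `"none"`. Secondary,
#' supplementary, and unmapped records are ignored. Assignment is
#' deterministic and independent of read order.
#'
#' @param alignments table from [read_alignments()].
#' @param index an [build_exon_index()] result.
#' @return data.frame `read_id`, `gene_id` (`NA` unless assigned),
#'   `status` (`"assigned"`, `"discarded_multi"`, `"none"`).
#' @export
assign_genes <- function(alignments, index) {
  alignments <- alignments[!alignments$is_secondary &
                           !alignments$is_supplementary &
                           !alignments$is_unmapped, , drop = FALSE]
  if (nrow(alignments) == 0L)
    return(data.frame(read_id = character(0), gene_id = character(0),
                      status = character(0), stringsAsFactors = FALSE))

  blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    alignments$cigar, pos = alignments$pos,
    ops = c("M", "=", "X", "D"), reduce.ranges = TRUE)
  n_blocks <- lengths(blocks)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(alignments$ref_name, n_blocks),
    ranges = unlist(blocks, use.names = FALSE))
  read_of_block <- rep(seq_len(nrow(alignments)), n_blocks)

  exons <- unlist(index$exons, use.names = FALSE)
  gene_of_exon <- rep(names(index$exons), lengths(index$exons))
  ov <- GenomicRanges::findOverlaps(gr, exons, ignore.strand = TRUE)

  hit_read <- read_of_block[S4Vectors::queryHits(ov)]
  hit_gene <- gene_of_exon[S4Vectors::subjectHits(ov)]
  genes_per_read <- lapply(
    split(hit_gene, factor(hit_read, levels = seq_len(nrow(alignments)))),
    unique)

  n_genes <- lengths(genes_per_read)
  status <- ifelse(n_genes == 0L, "none",
                   ifelse(n_genes == 1L, "assigned", "discarded_multi"))
  gene_id <- ifelse(n_genes == 1L,
                    vapply(genes_per_read, function(g)
                      if (length(g) == 1L) g else NA_character_,
                      character(1)),
                    NA_character_)
  data.frame(read_id = alignments$read_id, gene_id = gene_id,
             status = status, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Cluster read 3' ends into polyadenylation sites
#'
#' Single-linkage clustering of strand-aware genomic cleavage
#' coordinates within each gene: sorted 3' ends are split wherever
#' consecutive ends are more than `window` nt apart. Each cluster with at
#' least `min_support` reads becomes a site located at the modal end
#' (ties broken toward the most distal position). Sites are ranked 5' to
#' 3' along the transcript (`apa_rank` 1 = most proximal).
#'
#' @param ends data.frame with columns `gene_id`, `ref_strand`, `end3`
#'   (e.g. the tail table of [call_tails()] joined with gene
#'   assignments).
#' @param window single-linkage window in nt (default 24, the typical
#'   cleavage heterogeneity scale).
#' @param min_support minimum reads per site (default 2).
#' @return data.frame `gene_id`, `position`, `support`, `cluster_width`,
#'   `apa_rank`.
#' @export
call_polya_sites <- function(ends, window = 24L, min_support = 2L) {
  stopifnot(all(c("gene_id", "ref_strand", "end3") %in% names(ends)))
  ends <- ends[!is.na(ends$gene_id), , drop = FALSE]
  out <- lapply(split(ends, ends$gene_id), function(g) {
    strand <- g$ref_strand[1]
    pos <- sort(g$end3)
    cluster <- cumsum(c(1L, diff(pos) > window))
    sites <- lapply(split(pos, cluster), function(p) {
      if (length(p) < min_support) return(NULL)
      tab <- table(p)
      modes <- as.integer(names(tab)[tab == max(tab)])
      site <- if (strand == "+") max(modes) else min(modes)
      data.frame(gene_id = g$gene_id[1], position = site,
                 support = length(p),
                 cluster_width = max(p) - min(p),
                 stringsAsFactors = FALSE)
    })
    sites <- sites[!vapply(sites, is.null, logical(1))]
    if (!length(sites)) return(NULL)
    df <- do.call(rbind, sites)
    ord <- order(if (strand == "+") df$position else -df$position)
    df <- df[ord, , drop = FALSE]
    df$apa_rank <- seq_len(nrow(df))
    df
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(gene_id = character(0), position = integer(0),
                      support = integer(0), cluster_width = integer(0),
                      apa_rank = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify genes by number of polyadenylation sites
#'
#' Follows the convention that a gene with two called sites shows one
#' alternative-polyadenylation event: `"1 APA site"` for two sites,
#' `"2 APA sites"` for three, `">=3 APA sites"` beyond, and
#' `"single site"` for one.
#'
#' @param sites output of [call_polya_sites()].
#' @return data.frame `gene_id`, `n_sites`, `apa_class`.
#' @export
classify_apa_genes <- function(sites) {
  n <- table(sites$gene_id)
  cls <- function(k) {
    if (k == 1L) "single site"
    else if (k == 2L) "1 APA site"
    else if (k == 3L) "2 APA sites"
    else ">=3 APA sites"
  }
  data.frame(gene_id = names(n), n_sites = as.integer(n),
             apa_class = vapply(as.integer(n), cls, character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare called sites with a reference poly(A) site set
#'
#' @param sites output of [call_polya_sites()] with a `ref_name` column,
#'   or a `GRanges`; if `sites` lacks `ref_name`, supply single-chromosome
#'   data only.
#' @param reference a BED file path or a `GRanges` of reference sites.
#' @param slack maximum distance in nt for a match (default 24).
#' @param ref_name chromosome name(s) for the called sites when `sites`
#'   is a plain site table without one.
#' @return list with `fraction_overlapping` and per-site logical
#'   `matched`.
#' @export
compare_sites_to_reference <- function(sites, reference, slack = 24L,
                                       ref_name = NULL) {
  ref <- if (is.character(reference)) rtracklayer::import(reference)
         else reference
  if (length(ref) == 0L) {
    warning("empty reference site set; overlap fraction is 0")
    return(list(fraction_overlapping = 0,
                matched = rep(FALSE, nrow(sites))))
  }
  chroms <- sites$ref_name %||% ref_name
  if (is.null(chroms)) stop("site table needs ref_name (or pass ref_name=)")
  q <- GenomicRanges::GRanges(
    seqnames = chroms,
    ranges = IRanges::IRanges(start = sites$position, width = 1L))
  hits <- GenomicRanges::countOverlaps(
    q, ref, maxgap = slack, ignore.strand = TRUE) > 0L
  list(fraction_overlapping = mean(hits), matched = hits)
}

#' Group reads into isoforms by intron chain
#'
#' Reads with byte-identical intron chains (the ordered genomic
#' coordinates of their N-gap CIGAR runs, with chromosome and strand)
#' form one isoform; intronless reads on the same chromosome/strand form
#' a single chain class `"."`.
#'
#' @param alignments table from [read_alignments()].
#' @return data.frame `read_id`, `isoform` (chain signature string).
#' @export
group_isoforms <- function(alignments) {
  alignments <- alignments[!alignments$is_secondary &
                           !alignments$is_supplementary &
                           !alignments$is_unmapped, , drop = FALSE]
  sig <- vapply(seq_len(nrow(alignments)), function(i) {
    gaps <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      alignments$cigar[i], pos = alignments$pos[i], ops = "N")[[1]]
    chain <- if (length(gaps) == 0L) "."
             else paste(IRanges::start(gaps), IRanges::end(gaps),
                        sep = "-", collapse = ",")
    paste(alignments$ref_name[i], alignments$ref_strand[i], chain,
          sep = ":")
  }, character(1))
  data.frame(read_id = alignments$read_id, isoform = sig,
             stringsAsFactors = FALSE)
}
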