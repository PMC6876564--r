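#' Configuration for the synthetic CCS read generator
#'
#' Bundles every knob of the simulator with defaults chosen to emulate a
#' barcoded full-length cDNA CCS library: per-gene lognormal tail
#' lengths, a low internal non-A modification rate with 5'-biased
#' positions, occasional concatemers, and a high-pass consensus read
#' population. The seed fully determines the output.
#'
#' @param seed integer RNG seed.
#' @param samples character vector of sample (barcode) identifiers.
#' @param n_genes number of toy genes (default 20).
#' @param reads_per_sample reads simulated per sample (default 500).
#' @param transcript_length_range min/max transcript length in nt.
#' @param exons_per_gene_range min/max exon count per gene.
#' @param intron_length_range min/max intron length.
#' @param mu_log_range range of per-gene lognormal meanlog for tail
#'   length; defaults give geometric-mean tails of roughly 40-120 nt,
#'   the scale observed in transcriptionally quiescent oocytes.
#' @param sigma_log per-gene lognormal sdlog (default 0.25).
#' @param max_tail truncation ceiling for tail lengths (default 500 nt).
#' @param mod_rate mean per-base internal modification rate within tails
#'   (default 0.007, the bulk non-A frequency scale in tail bodies).
#' @param mod_positional_scale decay scale (fraction of tail length) of
#'   the 5'-biased exponential positional weight (default 0.3).
#' @param mod_base_probs named probabilities for the substituted base
#'   (`U` is written as `T`).
#' @param mod_g3_rate additional chance of a G placed in the 3'-most
#'   tenth of the tail, mirroring the secondary 3' G enrichment mode
#'   (default 0).
#' @param terminal_mod_rate chance of appending 1-2 non-A bases at the
#'   very 3' end of a tail (default 0).
#' @param error_rate per-base sequencing error rate (default 0; about
#'   0.002 matches the residual error of >=10-pass consensus reads).
#' @param error_shares substitution/insertion/deletion shares of
#'   `error_rate`.
#' @param concatemer_rate fraction of reads emitted as two-unit
#'   concatemers (default 0).
#' @param passes_lambda Poisson mean of the pass-number distribution
#'   (default 30; passes are `max(1, rpois(lambda))`).
#' @param apa_site_offsets candidate 3'-end offsets (nt upstream of the
#'   annotated transcript end) from which each gene draws 1-3 planted
#'   polyadenylation sites; offsets are separated by more than any
#'   customary clustering window.
#' @param five_prime_primer shared cDNA primer / template-switching
#'   oligo sequence.
#' @param min_passes_sim lower bound below which simulated pass counts
#'   are resampled (default 1; set 10 to emit only high-pass reads).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       samples = c("bc01", "bc02", "bc03"),
                       n_genes = 20L,
                       reads_per_sample = 500L,
                       transcript_length_range = c(500L, 1500L),
                       exons_per_gene_range = c(1L, 4L),
                       intron_length_range = c(60L, 200L),
                       mu_log_range = log(c(40, 120)),
                       sigma_log = 0.25,
                       max_tail = 500L,
                       mod_rate = 0.007,
                       mod_positional_scale = 0.3,
                       mod_base_probs = c(T = 0.45, G = 0.35, C = 0.2),
                       mod_g3_rate = 0,
                       terminal_mod_rate = 0,
                       error_rate = 0,
                       error_shares = c(sub = 0.6, ins = 0.2, del = 0.2),
                       concatemer_rate = 0,
                       passes_lambda = 30,
                       apa_site_offsets = c(0L, 120L, 240L),
                       five_prime_primer = "AAGCAGTGGTATCAACGCAGAGTAC",
                       min_passes_sim = 1L) {
  cfg <- as.list(environment())
  rates <- c(cfg$mod_rate, cfg$mod_g3_rate, cfg$terminal_mod_rate,
             cfg$error_rate, cfg$concatemer_rate)
  stopifnot(all(rates >= 0 & rates <= 1),
            cfg$n_genes >= 1L, cfg$reads_per_sample >= 1L,
            abs(sum(cfg$error_shares) - 1) < 1e-8,
            abs(sum(cfg$mod_base_probs) - 1) < 1e-8)
  class(cfg) <- "sim_config"
  cfg
}

# Barcodes with pairwise edit distance > 2 * max_edits, by rejection.
sample_barcodes <- function(n, len = 16L, min_dist = 5L) {
  bc <- character(0)
  guard <- 0L
  while (length(bc) < n) {
    cand <- random_dna(1, len)
    if (all(vapply(bc, edit_distance, integer(1), b = cand) >= min_dist))
      bc <- c(bc, cand)
    guard <- guard + 1L
    if (guard > 10000L) stop("cannot place barcodes at requested distance")
  }
  bc
}

# Toy gene models laid head-to-tail on one chromosome with 300-nt
# spacers. Returns list(genome=, genes=list of list(gene_id, strand,
# exons=data.frame(start,end), transcript, tx_len)).
build_toy_genome <- function(cfg) {
  genes <- vector("list", cfg$n_genes)
  cursor <- 301L
  layout <- list()
  for (g in seq_len(cfg$n_genes)) {
    tx_len <- sample(seq(cfg$transcript_length_range[1],
                         cfg$transcript_length_range[2]), 1L)
    k <- sample(seq(cfg$exons_per_gene_range[1],
                    cfg$exons_per_gene_range[2]), 1L)
    # split tx_len into k exon widths of at least 80 nt
    cuts <- sort(sample(seq(80L, tx_len - 80L * (k - 1L), by = 1L),
                        k - 1L, replace = FALSE))
    widths <- diff(c(0L, cuts, tx_len))
    while (any(widths < 40L)) {  # re-draw degenerate splits
      cuts <- sort(sample(seq(80L, tx_len - 80L * (k - 1L), by = 1L),
                          k - 1L, replace = FALSE))
      widths <- diff(c(0L, cuts, tx_len))
    }
    introns <- if (k > 1L)
      sample(seq(cfg$intron_length_range[1], cfg$intron_length_range[2]),
             k - 1L, replace = TRUE) else integer(0)
    starts <- integer(k); ends <- integer(k)
    pos <- cursor
    for (e in seq_len(k)) {
      starts[e] <- pos
      ends[e] <- pos + widths[e] - 1L
      pos <- ends[e] + 1L + (if (e < k) introns[e] else 0L)
    }
    strand <- sample(c("+", "-"), 1L)
    layout[[g]] <- list(gene_id = sprintf("gene%02d", g),
                        strand = strand,
                        exons = data.frame(start = starts, end = ends),
                        tx_len = tx_len)
    cursor <- ends[k] + 301L
  }
  genome <- random_dna(1, cursor + 300L)
  for (g in seq_along(layout)) {
    ex <- layout[[g]]$exons
    pieces <- vapply(seq_len(nrow(ex)), function(e)
      substr(genome, ex$start[e], ex$end[e]), character(1))
    tx <- paste(pieces, collapse = "")
    if (layout[[g]]$strand == "-") tx <- revcomp(tx)
    layout[[g]]$transcript <- tx
  }
  list(genome = genome, genes = layout)
}

# Genomic blocks (ascending) covered by the first cdna_len transcript
# bases of a gene; leftmost block start is the SAM POS.
transcript_blocks <- function(gene, cdna_len) {
  ex <- gene$exons
  widths <- ex$end - ex$start + 1L
  if (gene$strand == "+") {
    remaining <- cdna_len
    blocks <- list()
    for (e in seq_len(nrow(ex))) {
      take <- min(widths[e], remaining)
      if (take > 0L)
        blocks[[length(blocks) + 1L]] <-
          c(ex$start[e], ex$start[e] + take - 1L)
      remaining <- remaining - take
      if (remaining == 0L) break
    }
  } else {
    remaining <- cdna_len
    blocks <- list()
    for (e in rev(seq_len(nrow(ex)))) {
      take <- min(widths[e], remaining)
      if (take > 0L)
        blocks[[length(blocks) + 1L]] <-
          c(ex$end[e] - take + 1L, ex$end[e])
      remaining <- remaining - take
      if (remaining == 0L) break
    }
    blocks <- rev(blocks)
  }
  do.call(rbind, blocks)
}

# Draw one modified tail; returns list(seq, mods=data.frame(pos, base)).
draw_tail <- function(len, cfg) {
  bases <- rep("A", len)
  mods <- data.frame(pos = integer(0), base = character(0),
                     stringsAsFactors = FALSE)
  if (len > 0L && cfg$mod_rate > 0) {
    rel <- seq_len(len) / len
    w <- exp(-rel / cfg$mod_positional_scale)
    p <- pmin(cfg$mod_rate * w / mean(w), 1)
    hit <- which(runif(len) < p)
    if (length(hit)) {
      sub <- sample(names(cfg$mod_base_probs), length(hit),
                    replace = TRUE, prob = cfg$mod_base_probs)
      bases[hit] <- sub
      mods <- data.frame(pos = hit, base = sub, stringsAsFactors = FALSE)
    }
  }
  if (len > 0L && cfg$mod_g3_rate > 0) {
    tail_zone <- which(seq_len(len) / len > 0.9 & bases == "A")
    g3 <- tail_zone[runif(length(tail_zone)) < cfg$mod_g3_rate]
    if (length(g3)) {
      bases[g3] <- "G"
      mods <- rbind(mods, data.frame(pos = g3, base = "G",
                                     stringsAsFactors = FALSE))
    }
  }
  if (cfg$terminal_mod_rate > 0 && runif(1) < cfg$terminal_mod_rate) {
    k <- sample(1:2, 1L)
    term <- sample(c("T", "G", "C"), k, replace = TRUE)
    bases <- c(bases, term)
    mods <- rbind(mods, data.frame(pos = len + seq_len(k), base = term,
                                   stringsAsFactors = FALSE))
  }
  mods <- mods[order(mods$pos), , drop = FALSE]
  list(seq = paste(bases, collapse = ""), mods = mods)
}

# Substitution-only errors (length preserved).
inject_subs <- function(seq, rate) {
  if (rate <= 0 || !nzchar(seq)) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(b)) < rate)
  for (i in hit)
    b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
  paste(b, collapse = "")
}

# Full error model (substitutions + indels); used where length changes
# are tolerable (tails, adapters).
inject_errors <- function(seq, rate, shares) {
  if (rate <= 0 || !nzchar(seq)) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (i in seq_along(b)) {
    if (runif(1) < rate) {
      kind <- sample(c("sub", "ins", "del"), 1L, prob = shares)
      if (kind == "sub") {
        out <- c(out, sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L))
      } else if (kind == "ins") {
        out <- c(out, b[i], sample(c("A", "C", "G", "T"), 1L))
      }  # del: emit nothing
    } else {
      out <- c(out, b[i])
    }
  }
  paste(out, collapse = "")
}

#' Generate a synthetic barcoded CCS dataset with full ground truth
#'
#' Simulates reads of the library layout `5' primer + cDNA + poly(A)
#' tail + reverse complement of the sample probe` over a toy genome, and
#' emits, by construction (no aligner involved), SAM alignments of the
#' clean reads in which the tail appears as the 3'-terminal soft clip.
#' Substitution errors may fall anywhere; indel errors are confined to
#' the tail (elsewhere they would invalidate the constructed CIGAR), so
#' alignments stay exact while measured tail lengths degrade with the
#' error rate, as with a real aligner. Everything is deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, writes `reads.fastq`,
#'   `truth.tsv`, `genome.fa`, `annotation.gtf`, `alignments.sam`,
#'   `barcodes.tsv`, and `true_sites.bed`.
#' @return list with `reads` (FASTQ-equivalent read table), `truth`
#'   (per-read ground truth), `probes` (the [probe_set()]), `genome`
#'   (named sequence), `genes` (gene models), `gtf` (annotation lines),
#'   `sam` (alignment lines), `true_sites` (planted cleavage sites per
#'   gene), and `files` (paths, when `out_dir` was given).
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  barcodes <- sample_barcodes(length(config$samples))
  tso6 <- substr(config$five_prime_primer, 1L, 6L)
  probes <- probe_set(config$samples, paste0(barcodes, tso6),
                      five_prime_primer = config$five_prime_primer)

  toy <- build_toy_genome(config)
  genes <- toy$genes
  n_genes <- length(genes)

  mu_log <- runif(n_genes, config$mu_log_range[1], config$mu_log_range[2])
  n_sites <- sample(seq_along(config$apa_site_offsets), n_genes,
                    replace = TRUE)
  site_offsets <- lapply(n_sites, function(k) config$apa_site_offsets[1:k])

  # planted cleavage coordinates per gene and offset
  true_sites <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    offs <- site_offsets[[g]]
    pos <- vapply(offs, function(o) {
      blk <- transcript_blocks(genes[[g]], genes[[g]]$tx_len - o)
      if (genes[[g]]$strand == "+") blk[nrow(blk), 2] else blk[1, 1]
    }, numeric(1))
    data.frame(gene_id = genes[[g]]$gene_id, offset = offs,
               position = as.integer(pos),
               strand = genes[[g]]$strand, stringsAsFactors = FALSE)
  }))

  n_total <- length(config$samples) * config$reads_per_sample
  col <- function(proto) rep(proto, n_total)
  v <- list(read_id = col(NA_character_), sequence = col(NA_character_),
            num_passes = col(NA_integer_), sample = col(NA_character_),
            gene_id = col(NA_character_), cdna_len = col(NA_integer_),
            apa_offset = col(NA_integer_), tail_seq = col(NA_character_),
            true_tail_draw = col(NA_integer_), mods = col(NA_character_),
            n_mods = col(NA_integer_), is_concatemer = col(NA),
            flipped = col(NA), strand = col(NA_character_),
            end3 = col(NA_integer_), mu_log = col(NA_real_),
            clean_sequence = col(NA_character_))
  sam <- character(n_total)

  ridx <- 0L
  for (s in seq_along(config$samples)) {
    sample_id <- config$samples[s]
    probe <- probes$probe[s]
    probe_rc <- revcomp(probe)
    for (r in seq_len(config$reads_per_sample)) {
      ridx <- ridx + 1L
      read_id <- sprintf("sim/%06d/ccs", ridx)
      g <- sample.int(n_genes, 1L)
      gene <- genes[[g]]
      off <- sample(site_offsets[[g]], 1L)
      cdna_len <- gene$tx_len - off
      tail_len <- max(1L, min(config$max_tail,
                              round(rlnorm(1, mu_log[g], config$sigma_log))))
      tl <- draw_tail(tail_len, config)
      cdna <- substr(gene$transcript, 1L, cdna_len)

      np <- 0L
      while (np < config$min_passes_sim)
        np <- max(1L, rpois(1, config$passes_lambda))

      # error injection: substitutions in templated parts, full model in
      # the tail and adapters
      cdna_err <- inject_subs(cdna, config$error_rate *
                                config$error_shares[["sub"]])
      tail_err <- inject_errors(tl$seq, config$error_rate,
                                config$error_shares)
      primer_err <- inject_errors(config$five_prime_primer,
                                  config$error_rate, config$error_shares)
      adapter_err <- inject_errors(probe_rc, config$error_rate,
                                   config$error_shares)
      unit <- paste0(primer_err, cdna_err, tail_err, adapter_err)

      is_concat <- runif(1) < config$concatemer_rate
      if (is_concat) {
        g2 <- sample.int(n_genes, 1L)
        cdna2 <- substr(genes[[g2]]$transcript, 1L,
                        genes[[g2]]$tx_len -
                          sample(site_offsets[[g2]], 1L))
        tail2 <- draw_tail(max(1L, min(config$max_tail,
                                       round(rlnorm(1, mu_log[g2],
                                                    config$sigma_log)))),
                           config)$seq
        unit1 <- paste0(config$five_prime_primer, cdna2, tail2, probe_rc)
        unit <- paste0(inject_errors(unit1, config$error_rate,
                                     config$error_shares), unit)
      }

      flipped <- runif(1) < 0.5
      emitted <- if (flipped) revcomp(unit) else unit

      blk <- transcript_blocks(gene, cdna_len)
      end3 <- if (gene$strand == "+") blk[nrow(blk), 2] else blk[1, 1]

      v$read_id[ridx] <- read_id
      v$sequence[ridx] <- emitted
      v$num_passes[ridx] <- np
      v$sample[ridx] <- sample_id
      v$gene_id[ridx] <- gene$gene_id
      v$cdna_len[ridx] <- cdna_len
      v$apa_offset[ridx] <- off
      v$tail_seq[ridx] <- tl$seq
      v$true_tail_draw[ridx] <- tail_len
      v$mods[ridx] <- if (nrow(tl$mods))
        paste(tl$mods$pos, tl$mods$base, sep = ":", collapse = ";")
        else ""
      v$n_mods[ridx] <- nrow(tl$mods)
      v$is_concatemer[ridx] <- is_concat
      v$flipped[ridx] <- flipped
      v$strand[ridx] <- gene$strand
      v$end3[ridx] <- as.integer(end3)
      v$mu_log[ridx] <- mu_log[g]
      v$clean_sequence[ridx] <- paste0(cdna_err, tail_err)
      sam[ridx] <- sam_record(read_id, gene, blk, cdna_err, tail_err)
    }
  }
  reads <- data.frame(read_id = v$read_id, sequence = v$sequence,
                      num_passes = v$num_passes, source = "synthetic",
                      stringsAsFactors = FALSE)
  truth <- data.frame(
    read_id = v$read_id, sample = v$sample, gene_id = v$gene_id,
    cdna_len = v$cdna_len, apa_offset = v$apa_offset,
    tail_seq = v$tail_seq, tail_length = nchar(v$tail_seq),
    true_tail_draw = v$true_tail_draw, mods = v$mods, n_mods = v$n_mods,
    is_concatemer = v$is_concatemer, flipped = v$flipped,
    strand = v$strand, end3 = v$end3, num_passes = v$num_passes,
    mu_log = v$mu_log, clean_sequence = v$clean_sequence,
    stringsAsFactors = FALSE)

  gtf <- gtf_lines(genes)
  sam_lines <- c(sam_header(nchar(toy$genome)), sam)

  out <- list(reads = reads, truth = truth, probes = probes,
              genome = c(chrT = toy$genome), genes = genes, gtf = gtf,
              sam = sam_lines, true_sites = true_sites,
              barcodes = data.frame(barcode_id = config$samples,
                                    probe = probes$probe,
                                    five_prime_primer =
                                      config$five_prime_primer,
                                    stringsAsFactors = FALSE))
  if (!is.null(out_dir)) out$files <- write_sim_outputs(out, out_dir)
  out
}

sam_header <- function(genome_len) {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:chrT\tLN:%d", genome_len))
}

# One constructed SAM line: clean read (cDNA + tail) aligned over the
# gene's exon blocks with the tail as 3'-terminal soft clip.
sam_record <- function(read_id, gene, blocks, cdna, tail_seq) {
  widths <- blocks[, 2] - blocks[, 1] + 1L
  gaps <- if (nrow(blocks) > 1L)
    blocks[-1L, 1] - blocks[-nrow(blocks), 2] - 1L else integer(0)
  body <- paste0(widths, "M")
  if (length(gaps))
    body <- c(rbind(body[-length(body)], paste0(gaps, "N")),
              body[length(body)])
  body <- paste(body, collapse = "")
  tail_len <- nchar(tail_seq)
  clean <- paste0(cdna, tail_seq)
  if (gene$strand == "+") {
    cigar <- if (tail_len > 0L) paste0(body, tail_len, "S") else body
    flag <- 0L
    seq_stored <- clean
  } else {
    cigar <- if (tail_len > 0L) paste0(tail_len, "S", body) else body
    flag <- 16L
    seq_stored <- revcomp(clean)
  }
  paste(read_id, flag, "chrT", blocks[1, 1], 255L, cigar, "*", 0L, 0L,
        seq_stored, "*", sprintf("np:i:1"), sep = "\t")
}

gtf_lines <- function(genes) {
  unlist(lapply(genes, function(g) {
    vapply(seq_len(nrow(g$exons)), function(e) {
      sprintf(paste0("chrT\tccstail_sim\texon\t%d\t%d\t.\t%s\t.\t",
                     "gene_id \"%s\"; transcript_id \"%s.t1\";"),
              g$exons$start[e], g$exons$end[e], g$strand,
              g$gene_id, g$gene_id)
    }, character(1))
  }))
}

write_sim_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    reads = file.path(out_dir, "reads.fastq"),
    truth = file.path(out_dir, "truth.tsv"),
    genome = file.path(out_dir, "genome.fa"),
    gtf = file.path(out_dir, "annotation.gtf"),
    sam = file.path(out_dir, "alignments.sam"),
    barcodes = file.path(out_dir, "barcodes.tsv"),
    sites = file.path(out_dir, "true_sites.bed"))
  write_ccs(out$reads, files[["reads"]])
  utils::write.table(out$truth, files[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gn <- Biostrings::DNAStringSet(out$genome)
  Biostrings::writeXStringSet(gn, files[["genome"]])
  writeLines(out$gtf, files[["gtf"]])
  writeLines(out$sam, files[["sam"]])
  utils::write.table(out$barcodes, files[["barcodes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # BED is 0-based half-open
  bed <- sprintf("chrT\t%d\t%d\t%s\t0\t%s",
                 out$true_sites$position - 1L, out$true_sites$position,
                 out$true_sites$gene_id, out$true_sites$strand)
  writeLines(bed, files[["sites"]])
  files
}

#' Generate synthetic oligo(dT)-T30VN library reads for anchoring analysis
#'
#' Simulates reads of a conventional full-length cDNA library in which
#' the RT primer's VN end anchored either at the 3'-UTR/poly(A) junction
#' (model `a`: UTR followed directly by the terminal A-stretch) or
#' within the tail body (model `b`: UTR, a short stretch of genuine tail
#' A's, the 1-2 anchoring non-A base(s), then the terminal A-stretch).
#'
#' @param n_reads number of reads.
#' @param prop_b proportion of model-b reads (default 0.05).
#' @param prop_double_anchor among model-b reads, proportion anchored at
#'   two consecutive non-A bases (default 0.3).
#' @param utr_length_range range of simulated 3'-UTR lengths.
#' @param terminal_a_range range of terminal A-stretch lengths (T30
#'   complement; default 28-34).
#' @param body_a_range range of genuine-tail A-stretch lengths in model
#'   b reads (default 5-15).
#' @param seed RNG seed.
#' @return list with `reads` (data.frame `read_id`, `sequence`,
#'   `utr_end`) and `truth` (`model`, `anchor_bases`).
#' @export
generate_isoseq_vn <- function(n_reads = 1000L, prop_b = 0.05,
                               prop_double_anchor = 0.3,
                               utr_length_range = c(150L, 400L),
                               terminal_a_range = c(28L, 34L),
                               body_a_range = c(5L, 15L),
                               seed = 1L) {
  set.seed(seed)
  model <- ifelse(runif(n_reads) < prop_b, "b", "a")
  utr_len <- sample(seq(utr_length_range[1], utr_length_range[2]),
                    n_reads, replace = TRUE)
  # UTRs must not end in an A-run that could blur the junction
  utr <- vapply(utr_len, function(l)
    paste0(random_dna(1, l - 1L), sample(c("C", "G"), 1L)), character(1))
  term_a <- sample(seq(terminal_a_range[1], terminal_a_range[2]),
                   n_reads, replace = TRUE)
  anchor <- character(n_reads)
  seqs <- character(n_reads)
  for (i in seq_len(n_reads)) {
    if (model[i] == "b") {
      k <- if (runif(1) < prop_double_anchor) 2L else 1L
      anchor[i] <- paste(sample(c("T", "G", "C"), k, replace = TRUE),
                         collapse = "")
      body_a <- sample(seq(body_a_range[1], body_a_range[2]), 1L)
      seqs[i] <- paste0(utr[i], strrep("A", body_a), anchor[i],
                        strrep("A", term_a[i]))
    } else {
      seqs[i] <- paste0(utr[i], strrep("A", term_a[i]))
    }
  }
  list(
    reads = data.frame(read_id = sprintf("vn/%06d/ccs", seq_len(n_reads)),
                       sequence = seqs, utr_end = utr_len,
                       stringsAsFactors = FALSE),
    truth = data.frame(model = model, anchor_bases = anchor,
                       stringsAsFactors = FALSE))
}

#' Generate synthetic spike-in reads
#'
#' Error-free (or error-injected) full-length spike-in reads of the
#' layout `5' primer + barcode + reporter body + poly(A) + 3' primer`,
#' with half of the reads emitted reverse-complemented.
#'
#' @param design a [spikein_design()].
#' @param n_per_design reads per design (default 1000).
#' @param error_rate per-base error rate over the whole read (default 0).
#' @param error_shares substitution/insertion/deletion shares.
#' @param seed RNG seed.
#' @return data.frame `read_id`, `sequence`, `num_passes`, `design_id`
#'   (truth), `true_tail_length`.
#' @export
simulate_spikein_reads <- function(design, n_per_design = 1000L,
                                   error_rate = 0,
                                   error_shares = c(sub = 0.6, ins = 0.2,
                                                    del = 0.2),
                                   seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(design$designs))) {
    d <- design$designs[i, ]
    for (r in seq_len(n_per_design)) {
      read <- paste0(design$five_prime_primer, d$barcode, design$body,
                     strrep("A", d$designed_tail),
                     design$three_prime_primer)
      if (error_rate > 0)
        read <- inject_errors(read, error_rate, error_shares)
      if (runif(1) < 0.5) read <- revcomp(read)
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = sprintf("spk/%s/%05d", d$design_id, r),
        sequence = read, num_passes = 12L, design_id = d$design_id,
        true_tail_length = d$designed_tail, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
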