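plus_aln <- function(clip3, cdna_len = 50L, clip5 = 0L) {
  cig <- paste0(if (clip5 > 0L) paste0(clip5, "S") else "",
                cdna_len, "M",
                if (clip3 > 0L) paste0(clip3, "S") else "")
  list(read_id = "r", ref_name = "chrF", pos = 100L, cigar = cig,
       ref_strand = "+", is_secondary = FALSE, is_supplementary = FALSE,
       is_unmapped = FALSE)
}

test_that("the three acceptance criteria gate tails as specified", {
  set.seed(41)
  cdna <- random_dna(1, 50)

  # pure homopolymer of 20 is accepted
  call <- extract_tail(plus_aln(20L), paste0(cdna, strrep("A", 20)))
  expect_true(call$ok)
  expect_equal(call$tail_length, 20L)
  expect_equal(unname(call$counts[["A"]]), 20L)

  # 14-nt clip fails the length criterion
  call <- extract_tail(plus_aln(14L), paste0(cdna, strrep("A", 14)))
  expect_false(call$ok)
  expect_equal(call$reason, "short_clip")

  # 20-nt clip without a 5-A run fails the run criterion
  call <- extract_tail(plus_aln(20L), paste0(cdna, strrep("ACGT", 5)))
  expect_false(call$ok)
  expect_equal(call$reason, "no_A5_run")

  # 20 non-A residues is not < 20
  call <- extract_tail(plus_aln(40L),
                       paste0(cdna, strrep("A", 20), strrep("G", 20)))
  expect_false(call$ok)
  expect_equal(call$reason, "too_many_nonA")

  # 19 non-A in a 36-nt clip: count passes but fraction 19/36 >= 0.5 fails
  call <- extract_tail(plus_aln(38L),
                       paste0(cdna, strrep("A", 19), strrep("G", 19)))
  expect_false(call$ok)
  expect_equal(call$reason, "high_nonA_fraction")
})

test_that("minus-strand alignments yield the tail in read orientation", {
  set.seed(42)
  cdna <- random_dna(1, 60)
  tail <- paste0(strrep("A", 18), "G", strrep("A", 11))
  clean <- paste0(cdna, tail)
  aln <- list(read_id = "r", ref_name = "chrF", pos = 500L,
              cigar = "30S60M", ref_strand = "-",
              is_secondary = FALSE, is_supplementary = FALSE,
              is_unmapped = FALSE)
  call <- extract_tail(aln, clean)
  expect_true(call$ok)
  expect_equal(call$tail_seq, tail)
  expect_equal(unname(call$counts[["G"]]), 1L)
})

test_that("nonprimary, unmapped, and suspicious records are rejected", {
  set.seed(43)
  clean <- paste0(random_dna(1, 50), strrep("A", 20))
  aln <- plus_aln(20L)
  aln$is_secondary <- TRUE
  expect_equal(extract_tail(aln, clean)$reason, "nonprimary")
  aln <- plus_aln(20L)
  aln$is_supplementary <- TRUE
  expect_equal(extract_tail(aln, clean)$reason, "nonprimary")
  aln <- plus_aln(20L)
  aln$is_unmapped <- TRUE
  expect_equal(extract_tail(aln, clean)$reason, "unmapped")

  # a 5' clip that itself looks like a tail flags the read
  clean5 <- paste0(strrep("A", 30), random_dna(1, 50), strrep("A", 20))
  aln <- plus_aln(20L, cdna_len = 50L, clip5 = 30L)
  expect_equal(extract_tail(aln, clean5)$reason, "suspicious_5p_clip")

  # CIGAR inconsistent with the read length is refused
  expect_equal(extract_tail(plus_aln(20L), "ACGT")$reason,
               "seq_length_mismatch")
})

test_that("acceptance decisions match a brute-force criteria check", {
  set.seed(44)
  n <- 2000L
  for (i in seq_len(n)) {
    len <- sample(5:60, 1)
    seq <- if (runif(1) < 0.5) {
      # tail-like: mostly A with random contamination
      s <- rep("A", len)
      k <- sample(0:min(len, 25), 1)
      if (k > 0) s[sample(len, k)] <- sample(c("C", "G", "T"), k,
                                             replace = TRUE)
      paste(s, collapse = "")
    } else {
      random_dna(1, len)
    }
    expect_equal(tail_criteria(seq)$ok, tail_criteria_oracle(seq),
                 info = seq)
  }
})

test_that("geometric means match closed forms and respect AM-GM", {
  expect_equal(gene_geometric_mean(50), 50)
  expect_equal(gene_geometric_mean(c(25, 100)), 50)
  expect_equal(gene_geometric_mean(c(30, 30, 30)), 30)
  expect_equal(gene_geometric_mean(c(25, 100, 50)), 125000^(1 / 3))
  expect_error(gene_geometric_mean(numeric(0)))
  expect_error(gene_geometric_mean(c(10, 0)))
  set.seed(45)
  for (i in 1:50) {
    x <- sample(1:500, sample(2:30, 1), replace = TRUE)
    gm <- gene_geometric_mean(x)
    expect_lte(gm, mean(x) + 1e-12)
    if (length(unique(x)) > 1L) expect_lt(gm, mean(x))
  }
})

test_that("gene summaries apply the read floor and pool non-A ratios", {
  tails <- data.frame(
    gene_id = c("g1", "g1", "g1", "g2", "g2"),
    tail_length = c(25L, 100L, 50L, 40L, 60L),
    A = c(25L, 99L, 50L, 40L, 60L),
    stringsAsFactors = FALSE)
  out <- summarize_genes(tails, min_reads = 3L)
  expect_equal(out$gene_id, "g1")
  expect_equal(out$n_reads, 3L)
  expect_equal(out$geo_mean_length, 125000^(1 / 3))
  expect_equal(out$non_a_ratio, 1 / 175)
  all_genes <- summarize_genes(tails, min_reads = 1L)
  expect_equal(all_genes$gene_id, c("g1", "g2"))
})

test_that("length histograms conserve counts and bin long tails", {
  expect_equal(sum(length_distribution(integer(0))$count), 0L)
  one <- long_tail_table(c(50L, 205L))
  expect_equal(one$fraction, 0.5)
  hit <- one$table[one$table$count > 0, ]
  expect_equal(hit$bin_start, 200L)
  expect_equal(hit$bin_end, 220L)
  set.seed(46)
  lens <- pmax(1L, as.integer(round(rlnorm(500, log(80), 0.5))))
  h <- length_distribution(lens)
  expect_equal(sum(h$count), 500L)
})

test_that("call_tails recovers planted tails from constructed alignments", {
  set.seed(47)
  cdna <- random_dna(1, 80)
  tailp <- paste0(strrep("A", 25), "T", strrep("A", 10))
  sam <- tempfile(fileext = ".sam")
  write_test_sam(c(
    sam_line("ok", 0L, "chrF", 10L, "80M36S", paste0(cdna, tailp)),
    sam_line("low", 0L, "chrF", 10L, "80M36S", paste0(cdna, tailp)),
    sam_line("minus", 16L, "chrF", 10L, "36S80M",
             revcomp(paste0(cdna, tailp)))), sam)
  aln <- read_alignments(sam)
  reads <- data.frame(read_id = c("ok", "low", "minus"),
                      sequence = paste0(cdna, tailp),
                      num_passes = c(12L, 3L, 30L),
                      stringsAsFactors = FALSE)
  res <- call_tails(aln, reads, min_passes = 10L)
  expect_equal(sort(res$tails$read_id), c("minus", "ok"))
  expect_equal(unique(res$tails$tail_seq), tailp)
  expect_equal(unique(res$tails$tail_length), 36L)
  # strand-aware 3' end: plus ends at pos+80-1, minus at pos
  expect_equal(res$tails$end3[res$tails$read_id == "ok"], 89L)
  expect_equal(res$tails$end3[res$tails$read_id == "minus"], 10L)
})
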