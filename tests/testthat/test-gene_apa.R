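write_test_gtf <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

gtf_exon <- function(start, end, gene, strand = "+") {
  sprintf("chrF\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t\";",
          start, end, strand, gene, gene)
}

test_that("exon indices merge overlaps and drop duplicates", {
  gtf <- write_test_gtf(c(
    gtf_exon(100, 200, "gA"), gtf_exon(150, 250, "gA"),
    gtf_exon(150, 250, "gA"),                     # duplicated line
    gtf_exon(1000, 1200, "gB", "-")))
  idx <- build_exon_index(gtf)
  expect_equal(length(idx$exons), 2L)
  a <- idx$exons[["gA"]]
  expect_equal(length(a), 1L)
  expect_equal(GenomicRanges::start(a), 100L)
  expect_equal(GenomicRanges::end(a), 250L)
  expect_equal(unname(idx$strand["gB"]), "-")
})

test_that("gene assignment follows exon overlap and discards multi-gene hits", {
  gtf <- write_test_gtf(c(
    gtf_exon(100, 300, "gA"), gtf_exon(500, 800, "gB")))
  idx <- build_exon_index(gtf)
  sam <- tempfile(fileext = ".sam")
  set.seed(71)
  write_test_sam(c(
    sam_line("inA", 0L, "chrF", 120L, "100M", random_dna(1, 100)),
    sam_line("span", 0L, "chrF", 250L, "60M240N60M", random_dna(1, 120)),
    sam_line("between", 0L, "chrF", 320L, "100M", random_dna(1, 100)),
    sam_line("sec", 256L, "chrF", 120L, "100M", random_dna(1, 100))),
    sam)
  aln <- read_alignments(sam)
  asg <- assign_genes(aln, idx)
  expect_equal(asg$status[asg$read_id == "inA"], "assigned")
  expect_equal(asg$gene_id[asg$read_id == "inA"], "gA")
  expect_equal(asg$status[asg$read_id == "span"], "discarded_multi")
  expect_equal(asg$status[asg$read_id == "between"], "none")
  expect_false("sec" %in% asg$read_id)
  # order independence
  asg_rev <- assign_genes(aln[rev(seq_len(nrow(aln))), ], idx)
  expect_equal(asg_rev[order(asg_rev$read_id), "gene_id"],
               asg[order(asg$read_id), "gene_id"])
})

test_that("site clustering matches hand-worked cases", {
  ends <- function(e, strand = "+")
    data.frame(gene_id = "g", ref_strand = strand, end3 = e,
               stringsAsFactors = FALSE)
  one <- call_polya_sites(ends(c(1000L, 1003L)), window = 24L,
                          min_support = 2L)
  expect_equal(nrow(one), 1L)
  expect_equal(one$support, 2L)
  expect_equal(one$cluster_width, 3L)

  two <- call_polya_sites(ends(c(1000L, 1000L, 1050L, 1050L)),
                          window = 24L, min_support = 2L)
  expect_equal(nrow(two), 2L)
  expect_equal(two$position, c(1000L, 1050L))
  expect_equal(two$apa_rank, c(1L, 2L))
  expect_equal(classify_apa_genes(two)$apa_class, "1 APA site")

  same <- call_polya_sites(ends(rep(2000L, 5)), 24L, 2L)
  expect_equal(same$cluster_width, 0L)
  expect_equal(same$position, 2000L)

  # minus strand: rank 1 (most proximal) is the highest coordinate
  minus <- call_polya_sites(ends(c(500L, 500L, 700L, 700L), "-"), 24L, 2L)
  expect_equal(minus$position[minus$apa_rank == 1L], 700L)

  # modal position with tie broken toward the distal end
  tied <- call_polya_sites(ends(c(100L, 100L, 104L, 104L)), 24L, 2L)
  expect_equal(tied$position, 104L)
})

test_that("clustering equals an exhaustive single-linkage oracle", {
  set.seed(72)
  for (i in 1:40) {
    n <- sample(2:100, 1)
    pts <- sort(sample(1:2000, n, replace = TRUE))
    window <- sample(c(5L, 24L, 60L), 1)
    sites <- call_polya_sites(
      data.frame(gene_id = "g", ref_strand = "+", end3 = pts,
                 stringsAsFactors = FALSE),
      window = window, min_support = 1L)
    oracle <- single_linkage_oracle(pts, window)
    oracle_sizes <- sort(vapply(oracle, length, integer(1)))
    expect_equal(sort(sites$support), oracle_sizes)
    oracle_modes <- sort(vapply(oracle, function(cl) {
      tab <- table(cl)
      max(as.integer(names(tab)[tab == max(tab)]))
    }, numeric(1)))
    expect_equal(sort(sites$position), oracle_modes)
  }
})

test_that("APA classes follow the two-sites-equals-one-event convention", {
  sites <- data.frame(
    gene_id = c("g1", "g2", "g2", "g3", "g3", "g3",
                "g4", "g4", "g4", "g4"),
    position = 1:10, stringsAsFactors = FALSE)
  cls <- classify_apa_genes(sites)
  expect_equal(cls$apa_class[cls$gene_id == "g1"], "single site")
  expect_equal(cls$apa_class[cls$gene_id == "g2"], "1 APA site")
  expect_equal(cls$apa_class[cls$gene_id == "g3"], "2 APA sites")
  expect_equal(cls$apa_class[cls$gene_id == "g4"], ">=3 APA sites")
})

test_that("reference comparison respects slack and warns on empty sets", {
  sites <- data.frame(gene_id = "g", position = c(1000L, 5000L),
                      ref_name = "chrF", stringsAsFactors = FALSE)
  ref <- GenomicRanges::GRanges(
    "chrF", IRanges::IRanges(start = 1010, width = 1))
  cmp <- compare_sites_to_reference(sites, ref, slack = 24L)
  expect_equal(cmp$matched, c(TRUE, FALSE))
  expect_equal(cmp$fraction_overlapping, 0.5)
  expect_warning(
    none <- compare_sites_to_reference(sites, GenomicRanges::GRanges()),
    "empty")
  expect_equal(none$fraction_overlapping, 0)
  # BED round trip
  bed <- tempfile(fileext = ".bed")
  writeLines("chrF\t999\t1000\tsite1\t0\t+", bed)
  cmp_bed <- compare_sites_to_reference(sites, bed, slack = 24L)
  expect_equal(cmp_bed$matched, c(TRUE, FALSE))
})

test_that("isoform grouping keys on exact intron chains", {
  set.seed(73)
  sam <- tempfile(fileext = ".sam")
  write_test_sam(c(
    sam_line("i1", 0L, "chrF", 100L, "50M100N50M", random_dna(1, 100)),
    sam_line("i2", 0L, "chrF", 100L, "50M100N50M", random_dna(1, 100)),
    sam_line("i3", 0L, "chrF", 100L, "40M110N60M", random_dna(1, 100)),
    sam_line("i4", 0L, "chrF", 100L, "100M", random_dna(1, 100))), sam)
  iso <- group_isoforms(read_alignments(sam))
  expect_equal(iso$isoform[iso$read_id == "i1"],
               iso$isoform[iso$read_id == "i2"])
  expect_false(iso$isoform[iso$read_id == "i3"] ==
               iso$isoform[iso$read_id == "i1"])
  expect_equal(length(unique(iso$isoform)), 3L)
})
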