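# Shared fixture: three samples with well-separated probes.
make_probes <- function(seed = 31) {
  set.seed(seed)
  bcs <- ccstail:::sample_barcodes(3, len = 16, min_dist = 5)
  primer <- "AAGCAGTGGTATCAACGCAGAGTAC"
  probe_set(c("s1", "s2", "s3"), paste0(bcs, substr(primer, 1, 6)),
            five_prime_primer = primer)
}

build_read <- function(probes, sample_idx, cdna, tail = strrep("A", 60)) {
  paste0(probes$five_prime_primer, cdna, tail,
         revcomp(probes$probe[sample_idx]))
}

test_that("a canonical read is assigned, oriented, and trimmed", {
  probes <- make_probes()
  set.seed(32)
  cdna <- random_dna(1, 300)
  tail <- strrep("A", 60)
  raw <- build_read(probes, 2L, cdna, tail)
  res <- clean_read(list(read_id = "r1", sequence = raw, num_passes = 12L),
                    probes)
  expect_equal(res$status, "clean")
  expect_equal(res$barcode_id, "s2")
  expect_equal(res$sequence, paste0(cdna, tail))
  expect_true("adapter_trim" %in% res$trim_log$event)
  expect_true("primer5_trim" %in% res$trim_log$event)

  # same read stored reverse-complemented
  res_rc <- clean_read(list(read_id = "r1rc", sequence = revcomp(raw),
                            num_passes = 12L), probes)
  expect_equal(res_rc$status, "clean")
  expect_equal(res_rc$sequence, paste0(cdna, tail))
  expect_true("oriented_rc" %in% res_rc$trim_log$event)
})

test_that("reads matching two distinct barcodes are ambiguous", {
  probes <- make_probes()
  set.seed(33)
  raw <- paste0(random_dna(1, 80), revcomp(probes$probe[1]),
                random_dna(1, 80), revcomp(probes$probe[2]))
  res <- clean_read(list(read_id = "amb", sequence = raw,
                         num_passes = 10L), probes)
  expect_equal(res$status, "ambiguous")
})

test_that("concatemers keep only the 3'-most unit", {
  probes <- make_probes()
  set.seed(34)
  cdna_a <- random_dna(1, 200)
  cdna_b <- random_dna(1, 250)
  tail <- strrep("A", 40)
  unit_a <- build_read(probes, 1L, cdna_a, tail)
  unit_b <- build_read(probes, 1L, cdna_b, tail)
  res <- clean_read(list(read_id = "cat", sequence = paste0(unit_a, unit_b),
                         num_passes = 15L), probes)
  expect_equal(res$status, "clean")
  expect_equal(res$sequence, paste0(cdna_b, tail))
  expect_true("concatemer_trim" %in% res$trim_log$event)
})

test_that("orientation conflicts and short retainments are unassigned", {
  probes <- make_probes()
  set.seed(35)
  # same probe readable on both strands of one read
  raw <- paste0(random_dna(1, 80), probes$probe[1], random_dna(1, 80),
                revcomp(probes$probe[1]), random_dna(1, 10))
  res <- clean_read(list(read_id = "conf", sequence = raw,
                         num_passes = 10L), probes)
  expect_equal(res$status, "unassigned")
  expect_equal(res$reason, "orientation_conflict")

  short <- build_read(probes, 1L, random_dna(1, 10), strrep("A", 20))
  res <- clean_read(list(read_id = "short", sequence = short,
                         num_passes = 10L), probes)
  expect_equal(res$status, "unassigned")
  expect_equal(res$reason, "too_short")

  res <- clean_read(list(read_id = "none", sequence = random_dna(1, 200),
                         num_passes = 10L), probes)
  expect_equal(res$status, "unassigned")
  expect_equal(res$reason, "no_probe")
})

test_that("cleaning is idempotent on already-clean sequences", {
  probes <- make_probes()
  set.seed(36)
  clean_seq <- paste0(random_dna(1, 300), strrep("A", 60))
  res <- clean_read(list(read_id = "c", sequence = clean_seq,
                         num_passes = 10L), probes)
  # no probe remains, so the read cannot be re-assigned; it must not be
  # mangled into something else
  expect_equal(res$status, "unassigned")
  expect_equal(res$reason, "no_probe")
})

test_that("trimming never invents sequence and removes all probe copies", {
  probes <- make_probes()
  set.seed(37)
  for (i in 1:25) {
    cdna <- random_dna(1, sample(100:400, 1))
    raw <- build_read(probes, sample(3, 1), cdna)
    if (runif(1) < 0.5) raw <- revcomp(raw)
    res <- clean_read(list(read_id = "p", sequence = raw,
                           num_passes = 10L), probes)
    expect_equal(res$status, "clean")
    # output is a substring of the oriented input
    expect_true(grepl(res$sequence, raw, fixed = TRUE) ||
                grepl(res$sequence, revcomp(raw), fixed = TRUE))
    # no probe findable in the retained sequence
    for (p in probes$probe)
      expect_equal(nrow(find_probe(res$sequence, p, probes$max_edits)), 0L)
  }
})

test_that("demultiplexing is robust to edits within the probe", {
  probes <- make_probes()
  set.seed(38)
  n <- 150L
  truth <- sample(3L, n, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    probe_damaged <- corrupt_seq(probes$probe[truth[i]], sample(0:2, 1))
    raw <- paste0(probes$five_prime_primer, random_dna(1, 200),
                  strrep("A", 50), revcomp(probe_damaged))
    if (runif(1) < 0.5) revcomp(raw) else raw
  }, character(1))
  reads <- data.frame(read_id = sprintf("r%03d", seq_len(n)),
                      sequence = seqs, num_passes = 12L,
                      stringsAsFactors = FALSE)
  dm <- demux_reads(reads, probes)
  expect_equal(nrow(dm$clean), n)
  expect_equal(dm$clean$barcode_id,
               probes$barcode_id[truth[match(dm$clean$read_id,
                                             reads$read_id)]])
  expect_equal(sum(dm$details$status == "ambiguous"), 0L)
})

test_that("demux report counts reconcile with the input", {
  probes <- make_probes()
  set.seed(39)
  reads <- data.frame(
    read_id = c("good", "junk"),
    sequence = c(build_read(probes, 3L, random_dna(1, 150)),
                 random_dna(1, 150)),
    num_passes = c(11L, 11L), stringsAsFactors = FALSE)
  dm <- demux_reads(reads, probes)
  counts <- setNames(dm$report$count, dm$report$category)
  expect_equal(unname(counts["assigned:s3"]), 1L)
  expect_equal(unname(counts["unassigned:no_probe"]), 1L)
  expect_equal(
    sum(counts[names(counts) != "reads_with_concatemer_trims"]),
    nrow(reads))
  out <- tempfile()
  paths <- write_demux(dm, out)
  expect_true(file.exists(paths[["s3"]]))
  back <- read_ccs(paths[["s3"]])
  expect_equal(back$read_id, "good")
})
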