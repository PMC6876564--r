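test_that("transcript profiles count G/C/U exactly", {
  p <- profile_tail("AAAGAAAATAAA")
  expect_equal(unname(p$counts[c("G", "T", "C")]), c(1L, 1L, 0L))
  expect_equal(unname(p$ratios[["non_a"]]), 2 / 12)
  expect_equal(unname(p$ratios[["G"]]), 1 / 12)

  pure <- profile_tail(strrep("A", 50))
  expect_true(all(pure$ratios == 0))

  runs <- profile_tail("AAAGGAAAT")$runs
  expect_equal(runs$base, c("G", "T"))
  expect_equal(runs$length, c(2L, 1L))
})

test_that("base counts always conserve tail length", {
  set.seed(51)
  for (i in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(1:80, 1),
                      replace = TRUE, prob = c(.8, .05, .05, .05, .05)),
               collapse = "")
    p <- profile_tail(s)
    expect_equal(sum(p$counts), nchar(s))
    expect_equal(sum(p$runs$length),
                 nchar(s) - unname(p$counts[["A"]]))
  }
})

test_that("run spectra equal a regex-based brute force", {
  set.seed(52)
  tails <- vapply(1:300, function(i) {
    s <- rep("A", sample(15:80, 1))
    k <- sample(0:6, 1)
    if (k > 0) {
      at <- sample(length(s), k)
      s[at] <- sample(c("C", "G", "T"), k, replace = TRUE)
    }
    paste(s, collapse = "")
  }, character(1))
  spec <- run_spectrum(tails)
  oracle <- do.call(rbind, lapply(tails, run_spectrum_oracle))
  oracle$base[oracle$base == "T"] <- "U"
  oracle$cat <- ifelse(oracle$length >= 4, "4+", as.character(oracle$length))
  for (i in seq_len(nrow(spec))) {
    expect_equal(spec$count[i],
                 sum(oracle$base == spec$base[i] &
                     oracle$cat == spec$run_length[i]),
                 info = paste(spec$base[i], spec$run_length[i]))
  }
  # weighted sum equals total non-A count (4+ handled via the oracle)
  expect_equal(sum(oracle$length),
               sum(nchar(tails) - vapply(tails, function(s)
                 sum(strsplit(s, "")[[1]] == "A"), numeric(1))))
})

test_that("gene ratios pool counts rather than averaging ratios", {
  expect_equal(gene_non_a_ratio(c(paste0("G", strrep("A", 9)),
                                  strrep("A", 90))), 0.01)
  expect_equal(gene_non_a_ratio(strrep("A", 30)), 0)
  one <- "AAGAAAAAAA"
  expect_equal(gene_non_a_ratio(one),
               unname(profile_tail(one)$ratios[["non_a"]]))
})

test_that("internal non-A fractions strip terminal runs as documented", {
  res <- fraction_with_internal_non_a(c("AAAAAG", "AAGAAA", "AAAAAA"))
  expect_equal(res$raw, 2 / 3)
  expect_equal(res$internal, 1 / 3)
  expect_equal(sum(res$by_length$n), 3L)
  empty <- fraction_with_internal_non_a(character(0))
  expect_true(is.na(empty$raw))
})

test_that("planted modification rates are recovered from generated tails", {
  set.seed(53)
  cfg <- sim_config(seed = 530, n_genes = 6, reads_per_sample = 150,
                    samples = c("s1", "s2"), mod_rate = 0.02)
  sim <- generate_dataset(cfg)
  measured <- sum(sim$truth$n_mods) / sum(sim$truth$tail_length)
  tol <- 3 * sqrt(0.02 / sum(sim$truth$tail_length))
  expect_lt(abs(measured - 0.02), tol)
  # 5'-biased injection: more non-A in the 5' half of the relative profile
  prof <- positional_profile(sim$truth$tail_seq, k = 20)$relative
  freq <- prof$total / prof$sampled
  expect_gt(mean(freq[1:10]), mean(freq[11:20]))
})

test_that("VN anchoring separates junction and tail-body models", {
  set.seed(54)
  utr <- paste0(random_dna(1, 199), "C")
  expect_equal(
    classify_vn_anchor(paste0(utr, strrep("A", 30)), 200)$model, "a")
  b1 <- classify_vn_anchor(
    paste0(utr, strrep("A", 10), "G", strrep("A", 30)), 200)
  expect_equal(b1$model, "b")
  expect_equal(b1$n_anchor_non_a, 1L)
  expect_equal(b1$anchor_bases, "G")
  b2 <- classify_vn_anchor(
    paste0(utr, strrep("A", 10), "GG", strrep("A", 30)), 200)
  expect_equal(b2$model, "b")
  expect_equal(b2$n_anchor_non_a, 2L)
  nc <- classify_vn_anchor(paste0(utr, strrep("A", 10)), 200)
  expect_equal(nc$model, "not_classifiable")
  expect_equal(nc$reason, "no_terminal_a_run")
})

test_that("planted anchoring-model proportions are recovered", {
  vn <- generate_isoseq_vn(n_reads = 800, prop_b = 0.08, seed = 55)
  s <- vn_anchor_summary(vn$reads$sequence, vn$reads$utr_end)
  expect_equal(s$calls$model, vn$truth$model)
  planted <- 100 * mean(vn$truth$model == "b")
  expect_equal(s$percent_model_b, planted)
  # anchor base identities recovered exactly
  bcalls <- s$calls$anchor_bases[s$calls$model == "b"]
  expect_equal(bcalls, vn$truth$anchor_bases[vn$truth$model == "b"])

  pure_a <- generate_isoseq_vn(n_reads = 100, prop_b = 0, seed = 56)
  sa <- vn_anchor_summary(pure_a$reads$sequence, pure_a$reads$utr_end)
  expect_equal(sum(sa$calls$model == "b"), 0L)
})

test_that("pass filtering is monotone in the threshold", {
  set.seed(57)
  reads <- data.frame(read_id = sprintf("r%d", 1:100),
                      sequence = random_dna(100, 30),
                      num_passes = sample(1:40, 100, replace = TRUE),
                      stringsAsFactors = FALSE)
  counts <- vapply(1:30, function(k) nrow(filter_by_passes(reads, k)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})
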