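# Independent brute-force oracles, deliberately implemented with
# different primitives than the package code they check.

# Semi-global (infix) edit distance of `pattern` against every substring
# of `subject`: full O(n*m) DP matrix, free start (row 0 = 0) and free
# end. Returns the minimum distance and the distance at every end column.
infix_dp_oracle <- function(subject, pattern) {
  s <- strsplit(toupper(subject), "", fixed = TRUE)[[1]]
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  n <- length(s); m <- length(p)
  D <- matrix(0L, nrow = m + 1L, ncol = n + 1L)
  D[, 1L] <- 0:m
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      mism <- p[i] != s[j] || p[i] == "N" || s[j] == "N"
      D[i + 1L, j + 1L] <- min(D[i, j] + mism, D[i, j + 1L] + 1L,
                               D[i + 1L, j] + 1L)
    }
  }
  end_row <- D[m + 1L, -1L]
  list(min_dist = min(end_row), by_end = end_row)
}

# Character-by-character re-check of the three tail acceptance criteria.
tail_criteria_oracle <- function(seq, min_len = 15L, max_non_a = 20L,
                                 max_non_a_frac = 0.5, min_a_run = 5L) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  len <- length(chars)
  if (len < min_len) return(FALSE)
  best_run <- 0L; run <- 0L
  non_a <- 0L
  for (c in chars) {
    if (c == "A") {
      run <- run + 1L
      if (run > best_run) best_run <- run
    } else {
      run <- 0L
      non_a <- non_a + 1L
    }
  }
  if (best_run < min_a_run) return(FALSE)
  if (non_a >= max_non_a) return(FALSE)
  if (non_a / len >= max_non_a_frac) return(FALSE)
  TRUE
}

# Single-linkage clusters of 1-D points within `window`, via pairwise
# union-find rather than the sorted-gap shortcut used in the package.
single_linkage_oracle <- function(points, window) {
  n <- length(points)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && abs(points[i] - points[j]) <= window) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  unname(split(points, comp))
}

# Maximal same-base non-A runs via regular expressions.
run_spectrum_oracle <- function(tail_seq) {
  m <- gregexpr("G+|C+|T+|N+", toupper(tail_seq))[[1]]
  if (m[1] == -1L) return(data.frame(base = character(0),
                                     length = integer(0)))
  data.frame(base = substr(rep(toupper(tail_seq), length(m)), m, m),
             length = attr(m, "match.length"))
}

# Corrupt a sequence with exactly k random edits (substitution,
# insertion, or deletion), for demultiplexing robustness tests.
corrupt_seq <- function(seq, k) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (e in seq_len(k)) {
    op <- sample(c("sub", "ins", "del"), 1L)
    i <- sample(length(b), 1L)
    if (op == "sub") {
      b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
    } else if (op == "ins") {
      b <- append(b, sample(c("A", "C", "G", "T"), 1L), after = i)
    } else if (length(b) > 1L) {
      b <- b[-i]
    }
  }
  paste(b, collapse = "")
}

# Minimal SAM writer for hand-built alignment fixtures.
write_test_sam <- function(records, path, sq = c(chrF = 5000L)) {
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  writeLines(c(header, records), path)
  path
}

sam_line <- function(qname, flag, rname, pos, cigar, seq) {
  paste(qname, flag, rname, pos, 255L, cigar, "*", 0L, 0L, seq, "*",
        sep = "\t")
}
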