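# Independent exhaustive-DP oracle for optimal local alignment score under
# affine gaps (gap of length L costs gap_open + gap_extend * L). Written
# before and independently of the package's alignment backend; pure R,
# O(m*n), three-state Gotoh recursion with a zero floor.
sw_oracle <- function(query, subject, match = 2, mismatch = -3,
                      gap_open = 5, gap_extend = 2) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  m <- length(q); n <- length(s)
  NEG <- -1e9
  M <- matrix(0, m + 1, n + 1)    # alignment ends in a match/mismatch
  X <- matrix(NEG, m + 1, n + 1)  # ends in a gap in the subject
  Y <- matrix(NEG, m + 1, n + 1)  # ends in a gap in the query
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sub <- if (q[i] == s[j] && q[i] != "N") match else mismatch
      M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + sub
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
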