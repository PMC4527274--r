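# Independent brute-force oracles used across the suite. These are
# deliberately written as plain per-position loops, independent of the
# package's vectorized implementations.

# Exhaustive EF-hand rule check at a single offset (1-based).
oracle_window_passes <- function(chars, s, loop_min_donors = 3) {
  de <- function(ch) ch == "D" || ch == "E"
  donor <- function(ch) ch %in% c("D", "E", "N", "Q", "S", "T")
  if (s + 35 > length(chars)) return(FALSE)
  w <- chars[s:(s + 35)]
  n_donors <- 0
  for (p in c(13, 15, 17, 19, 21, 24)) {
    if (donor(w[p])) n_donors <- n_donors + 1
  }
  de(w[14]) && de(w[22]) && de(w[24]) && n_donors >= loop_min_donors
}

# All-offsets brute force + greedy left-to-right selection.
oracle_scan <- function(seq, loop_min_donors = 3) {
  chars <- strsplit(seq, "")[[1]]
  passing <- c()
  for (s in seq_len(length(chars) - 35)) {
    if (oracle_window_passes(chars, s, loop_min_donors)) {
      passing <- c(passing, s)
    }
  }
  kept <- c()
  next_free <- 1
  for (s in passing) {
    if (s >= next_free) {
      kept <- c(kept, s)
      next_free <- s + 36
    }
  }
  as.integer(kept)
}

random_protein <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

# From-scratch Tajima constants, written independently of tajima_d().
oracle_tajima_d <- function(m, n, S, pi) {
  a1 <- 0; a2 <- 0
  for (i in 1:(m - 1)) {
    a1 <- a1 + 1 / i
    a2 <- a2 + 1 / i^2
  }
  b1 <- (m + 1) / (3 * (m - 1))
  b2 <- 2 * (m^2 + m + 3) / (9 * m * (m - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (m + 2) / (a1 * m) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi * n - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Exhaustive pair-loop diversity on a gap-free character matrix.
oracle_pairwise_pi <- function(mat) {
  m <- nrow(mat)
  total <- 0
  pairs <- 0
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      total <- total + mean(mat[i, ] != mat[j, ])
      pairs <- pairs + 1
    }
  }
  total / pairs
}

records_from_seqs <- function(...) {
  seqs <- c(...)
  cblkit::protein_records(paste0("rec", seq_along(seqs)), seqs)
}
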