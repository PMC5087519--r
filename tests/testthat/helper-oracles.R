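# Independent brute-force oracles used across the suite.

# Inertia moment by explicit triple loop over THSP rows and transitions:
# builds the co-occurrence counts pair by pair, normalizes each row by the
# times its first gray level occurred, then sums M_ij (i - j)^2.
im_bruteforce <- function(thsp, gray_levels) {
  counts <- matrix(0, gray_levels, gray_levels)
  for (r in seq_len(nrow(thsp))) {
    for (t in seq_len(ncol(thsp) - 1)) {
      i <- thsp[r, t] + 1
      j <- thsp[r, t + 1] + 1
      counts[i, j] <- counts[i, j] + 1
    }
  }
  im <- 0
  for (i in seq_len(gray_levels)) {
    row_total <- sum(counts[i, ])
    if (row_total == 0) next
    for (j in seq_len(gray_levels)) {
      im <- im + counts[i, j] / row_total * ((i - 1) - (j - 1))^2
    }
  }
  im
}

# Symmetric normalized GLCM by explicit pair enumeration for one offset.
glcm_bruteforce <- function(q, levels, drow, dcol) {
  counts <- matrix(0, levels, levels)
  h <- nrow(q); w <- ncol(q)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + drow; c2 <- c + dcol
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
        counts[q[r, c] + 1, q[r2, c2] + 1] <-
          counts[q[r, c] + 1, q[r2, c2] + 1] + 1
        counts[q[r2, c2] + 1, q[r, c] + 1] <-
          counts[q[r2, c2] + 1, q[r, c] + 1] + 1
      }
    }
  }
  counts / sum(counts)
}

# small random THSP generator for property tests
random_thsp <- function(h, t, g) {
  matrix(sample(0:(g - 1), h * t, replace = TRUE), h, t)
}
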