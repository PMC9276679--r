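# Independent brute-force oracles. These deliberately use naive double loops
# and recompute everything from the definitions, so they share no code with
# the package implementations they check.

# Square-ring (Chebyshev) RDF by direct pair enumeration with edge-truncated
# ring normalisation. pos: 1-based (row, col) matrix.
rdf_oracle <- function(pos, L, M) {
  n <- nrow(pos)
  g <- numeric(M)
  all_r <- rep(seq_len(L), times = L)
  all_c <- rep(seq_len(L), each = L)
  for (j in seq_len(M)) {
    acc <- 0
    for (i in seq_len(n)) {
      cnt <- 0
      for (k in seq_len(n)) {
        if (k == i) next
        d <- max(abs(pos[i, 1] - pos[k, 1]), abs(pos[i, 2] - pos[k, 2]))
        if (d == j) cnt <- cnt + 1
      }
      dall <- pmax(abs(all_r - pos[i, 1]), abs(all_c - pos[i, 2]))
      ring <- sum(dall == j)
      acc <- acc + cnt / ring
    }
    g[j] <- (acc / n) / (n / L^2)
  }
  g
}

# SAM by explicit per-distance loops over the envelope definition.
sam_oracle <- function(Ro, Rs, thresh, widen = 0.2) {
  M <- ncol(Ro)
  N <- nrow(Rs)
  hits <- 0
  for (j in seq_len(M)) {
    hi <- -Inf; lo <- Inf
    for (i in seq_len(nrow(Ro))) {
      hi <- max(hi, Ro[i, j]); lo <- min(lo, Ro[i, j])
    }
    u <- hi + widen * (hi - lo)
    l <- max(lo - widen * (hi - lo), 0)
    cnt <- 0
    for (k in seq_len(N)) if (Rs[k, j] > l && Rs[k, j] < u) cnt <- cnt + 1
    if (cnt / N >= thresh) hits <- hits + 1
  }
  hits / M
}

varsam_oracle <- function(Ro, Rs, window = 15) {
  w <- min(window, ncol(Ro), ncol(Rs))
  a <- max(Ro[, seq_len(w)]) - min(Ro[, seq_len(w)])
  b <- max(Rs[, seq_len(w)]) - min(Rs[, seq_len(w)])
  if (a == 0 || b == 0) return(0)
  min(a / b, b / a)
}

# random positive RDF-like matrices for property tests
random_rdf_matrix <- function(nrow, M, scale = 2) {
  matrix(abs(rnorm(nrow * M, mean = 1, sd = scale / 2)), nrow, M)
}
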