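# Shared fixtures and independent oracle implementations. The oracles
# deliberately avoid the code paths they check: the naive-decoding oracle
# multiplies raw probabilities (no logs), and the hard-decoding oracle
# scores codewords with an explicit per-position cost loop.

blob_centers3 <- rbind(c(0, 0), c(10, 0), c(0, 10))

make_blobs <- function(seed, n = 100L, sigma = 1, centers = blob_centers3) {
  gaussian_blobs(centers, n_per_class = n, sigma = sigma, seed = seed)
}

# Direct product-then-normalize naive decoder (independence assumption,
# probability space).
naive_oracle <- function(code, g) {
  K <- nrow(code)
  mass <- numeric(K)
  for (k in seq_len(K)) {
    prod_k <- 1
    for (i in seq_len(ncol(code))) {
      m <- code[k, i]
      if (is.na(m)) next
      prod_k <- prod_k * if (m == 1L) g[i] else (1 - g[i])
    }
    mass[k] <- prod_k
  }
  mass / sum(mass)
}

# Exhaustive nearest-codeword search with explicit modified-Hamming costs.
hard_oracle <- function(code, g, cutoff = 0.5) {
  z <- as.integer(g >= cutoff)
  best_k <- NA_integer_
  best_d <- Inf
  for (k in seq_len(nrow(code))) {
    d <- 0
    for (i in seq_len(ncol(code))) {
      a <- code[k, i]
      b <- z[i]
      d <- d + if (is.na(a) || is.na(b)) 0.5 else if (a == b) 0 else 1
    }
    if (d < best_d) {
      best_d <- d
      best_k <- k
    }
  }
  best_k
}

# A random valid coding matrix plus matching random outputs, for oracle
# equivalence sweeps. Column uniqueness caps the usable L: a dense code over
# K classes has at most 2^K - 2 distinct valid columns.
random_decode_instance <- function(K, L, kind) {
  L <- min(L, 2^K - 2L)
  L <- max(L, ceiling(log2(K)))
  code <- random_code_matrix(K, L, kind = kind, n_candidates = 1L,
                             seed = sample.int(1e6, 1L))
  list(code = code, g = stats::runif(ncol(code)))
}
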