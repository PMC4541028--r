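# Shared fixtures and independent oracles for the test suite.

# family of constant curves at the given heights
constant_family <- function(heights, K = 5) {
  matrix(heights, length(heights), K)
}

# Independent brute-force modified band depth: explicit triple loop over
# unordered pairs and grid points, written directly from the definition and
# sharing no code with the package kernels.
mbd_oracle <- function(v) {
  n <- nrow(v)
  K <- ncol(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        inside <- 0
        for (k in seq_len(K)) {
          lo <- min(v[a, k], v[b, k])
          hi <- max(v[a, k], v[b, k])
          if (v[i, k] >= lo && v[i, k] <= hi) inside <- inside + 1
        }
        acc <- acc + inside / K
      }
    }
    out[i] <- acc / choose(n, 2)
  }
  out
}

# random curve family; integer-valued with prob tie_prob to force pointwise ties
random_family <- function(n, K, tie_prob = 0.5) {
  if (stats::runif(1) < tie_prob) {
    matrix(sample(0:3, n * K, replace = TRUE), n, K)
  } else {
    matrix(stats::rnorm(n * K), n, K)
  }
}

# periodogram object with prescribed ordinates, for fixture-driven GCV tests
fake_periodogram <- function(power, fs = NULL) {
  K <- length(power)
  T <- 2L * (K - 1L)
  if (is.null(fs)) fs <- T
  structure(list(power = power, freq = (seq_len(K) - 1) * fs / T,
                 T = T, fs = fs, constant = FALSE),
            class = "periodogram")
}
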