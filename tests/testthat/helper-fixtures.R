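# shared fixture builders; everything is generated in code under fixed seeds

# random fingerprint matrix with per-row densities drawn in [dmin, dmax]
random_fp <- function(n, L, dmin = 0.05, dmax = 0.5) {
  dens <- runif(n, dmin, dmax)
  m <- matrix(0L, n, L)
  for (i in seq_len(n)) m[i, ] <- rbinom(L, 1L, dens[i])
  # avoid all-zero rows so similarity conventions do not fire in bulk tests
  zero <- rowSums(m) == 0L
  m[zero, 1L] <- 1L
  rownames(m) <- sprintf("c%04d", seq_len(n))
  m
}

# small labelled dataset + fit used across procedure tests
small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- simulate_dataset(synth_config(n_active = 40, n_inactive = 120,
                                         fp_length = 256),
                            seed = 101)
      cache <<- list(data = d, fit = ar_consensus(d))
    }
    cache
  }
})

# default-sized fixture and fit (slow-ish; built once per test run)
default_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- make_training_fixture(seed = 1)
      cache <<- list(data = d, fit = ar_consensus(d))
    }
    cache
  }
})
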