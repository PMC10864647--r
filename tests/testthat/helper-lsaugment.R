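# Shared fixture builders. All fixtures are generated in code with fixed
# seeds; nothing is read from disk.

# Small chromatography-like data set (3 experiments x 12 fractions).
tiny_ds <- function(noise_sd = 0, n_experiments = 3, n_fractions = 12,
                    seed = 7) {
  make_dataset(ds1_like_spec(noise_sd = noise_sd,
                             n_experiments = n_experiments,
                             n_fractions = n_fractions, seed = seed))
}

# Random spectral dataset without structure (for plumbing tests).
random_ds <- function(M = 8, N = 6, P = 2, seed = 1) {
  set.seed(seed)
  spectral_dataset(matrix(runif(M * N), M), matrix(runif(M * P), M),
                   wavelengths = seq(240, by = 2, length.out = N),
                   component_names = paste0("c", seq_len(P)),
                   groups = rep(c("a", "b"), length.out = M))
}

# Exact Shapley values by coalition enumeration (single background row).
exact_shapley <- function(f, x, bg) {
  N <- length(x)
  phi <- numeric(N)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), N))
  vals <- apply(subsets, 1L, function(m) {
    z <- bg
    z[as.logical(m)] <- x[as.logical(m)]
    f(matrix(z, 1L))[1L]
  })
  key <- apply(subsets, 1L, function(m) paste(as.integer(m), collapse = ""))
  val_of <- stats::setNames(vals, key)
  for (j in seq_len(N)) {
    for (r in seq_len(nrow(subsets))) {
      m <- as.logical(subsets[r, ])
      if (m[j]) next
      s <- sum(m)
      w <- factorial(s) * factorial(N - s - 1) / factorial(N)
      m2 <- m
      m2[j] <- TRUE
      k1 <- paste(as.integer(m2), collapse = "")
      k0 <- paste(as.integer(m), collapse = "")
      phi[j] <- phi[j] + w * (val_of[[k1]] - val_of[[k0]])
    }
  }
  phi
}
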