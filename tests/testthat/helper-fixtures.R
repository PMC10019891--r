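# shared fixtures: small configurations that keep tests fast

tiny_config <- function(seed = 42L, ...) {
  sim_config(n_subjects = 2L, n_blocks = 4L, trials_per_block = 6L,
             n_voxels = 12L, seed = seed, ...)
}

default_basis <- function() channel_basis()

# brute-force cosine-similarity oracle (double loop)
cosine_oracle <- function(X) {
  n <- nrow(X)
  S <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      S[i, j] <- sum(X[i, ] * X[j, ]) /
        (sqrt(sum(X[i, ]^2)) * sqrt(sum(X[j, ]^2)))
    }
  }
  S
}

# per-voxel normal-equations least-squares oracle for W
ols_oracle <- function(B1, C1) {
  t(apply(B1, 1, function(bv) {
    solve(C1 %*% t(C1), C1 %*% bv)
  }))
}

# noiseless subject: zero jitter keeps labels exactly at channel centers
noiseless_subject <- function(n_blocks = 4L, trials_per_block = 9L,
                              n_voxels = 15L, seed = 3L) {
  cfg <- sim_config(n_subjects = 1L, n_blocks = n_blocks,
                    trials_per_block = trials_per_block,
                    n_voxels = n_voxels, jitter_range = c(0, 0),
                    snr_cued = 1, noise_sd = 0, noise_cov_strength = 0,
                    lapse_rate = 0, recall_sd = 0, seed = seed)
  simulate_subject(cfg, 1)
}
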