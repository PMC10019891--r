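test_that("weight estimation matches the per-voxel normal-equations oracle", {
  set.seed(10)
  for (i in 1:25) {
    m <- sample(5:30, 1); n <- sample(15:60, 1)
    b <- default_basis()
    C1 <- design_matrix(b, runif(n, 0, 180))
    B1 <- matrix(rnorm(m * n), m, n)
    W <- estimate_weights(B1, C1)
    expect_equal(unname(W), unname(ols_oracle(B1, C1)), tolerance = 1e-10)
  }
})

test_that("identity designs and noiseless data are solved exactly", {
  set.seed(1)
  B1 <- matrix(rnorm(9 * 9), 9, 9)
  expect_equal(estimate_weights(B1, diag(9)), B1, tolerance = 1e-12)
  # consistency: B1 = W_true C1 recovers W_true
  b <- default_basis()
  C1 <- design_matrix(b, runif(50, 0, 180))
  W_true <- matrix(runif(20 * 9), 20, 9)
  expect_equal(estimate_weights(W_true %*% C1, C1), W_true,
               tolerance = 1e-9)
})

test_that("rank-deficient designs fall back to the pseudo-inverse with a warning", {
  b <- default_basis()
  C1 <- design_matrix(b, rep(40, 12))  # single repeated label
  B1 <- matrix(rnorm(5 * 12), 5, 12)
  expect_warning(W <- estimate_weights(B1, C1), "singular|rank")
  expect_true(all(is.finite(W)))
})

test_that("optimal filters have unit gain on their own channel", {
  set.seed(2)
  b <- default_basis()
  for (i in 1:10) {
    m <- sample(10:25, 1)
    C1 <- design_matrix(b, runif(60, 0, 180))
    B1 <- matrix(rnorm(m * 60), m, 60)
    for (cv in c("shrinkage", "identity")) {
      f <- estimate_noise_filters(B1, C1, cov = cv)
      expect_equal(unname(diag(crossprod(f$V, f$W))), rep(1, 9),
                   tolerance = 1e-10)
    }
  }
})

test_that("identity covariance reduces filters to normalized weights", {
  set.seed(3)
  b <- default_basis()
  C1 <- design_matrix(b, runif(40, 0, 180))
  B1 <- matrix(rnorm(12 * 40), 12, 40)
  W <- estimate_weights(B1, C1)
  f <- estimate_noise_filters(B1, C1, W, cov = "identity")
  expect_equal(f$V, W %*% diag(1 / colSums(W^2)), tolerance = 1e-12)
})

test_that("shrinkage vanishes and the covariance approaches the sample covariance at large n", {
  # anisotropic residuals: the scaled-identity target is wrong, so the
  # analytic coefficient must vanish as n grows
  set.seed(4)
  m <- 6
  scales <- seq(0.5, 2.5, length.out = m)
  X <- matrix(rnorm(m * 4000), m, 4000) * scales
  sh <- wmiem:::.shrink_covariance(X)
  expect_lt(sh$intensity, 0.02)
  brute <- X %*% t(X) / (ncol(X) - 1)  # uncentered, n - 1 convention
  expect_equal(sh$sigma, brute, tolerance = 0.02)
  # low n forces stronger regularization
  sh_small <- wmiem:::.shrink_covariance(X[, 1:12])
  expect_gt(sh_small$intensity, sh$intensity)
  # isotropic residuals are the degenerate case: target equals truth and
  # the coefficient approaches 1 instead
  X0 <- matrix(rnorm(m * 4000), m, 4000)
  expect_gt(wmiem:::.shrink_covariance(X0)$intensity, 0.5)
})

test_that("zero-residual training data triggers the identity fallback yet decodes finitely", {
  b <- default_basis()
  C1 <- design_matrix(b, b$centers)
  W_true <- generate_tuning_weights(10, b, seed = 5)
  B1 <- W_true[, 1] %*% C1[1, , drop = FALSE]  # channel 1 explains all of B1
  expect_warning(f <- estimate_noise_filters(B1, C1, W = W_true),
                 "all-zero residuals")
  C2 <- invert_channels(f, matrix(rnorm(10 * 3), 10, 3))
  expect_true(all(is.finite(C2)))
})

test_that("inversion is the stated linear map", {
  set.seed(6)
  b <- default_basis()
  C1 <- design_matrix(b, runif(50, 0, 180))
  B1 <- matrix(rnorm(15 * 50), 15, 50)
  f <- estimate_noise_filters(B1, C1)
  # unit-gain construction: decoding a channel's own weight vector gives 1
  for (i in c(1, 5, 9)) {
    expect_equal(invert_channels(f, f$W[, i, drop = FALSE])[i, 1], 1,
                 tolerance = 1e-10)
  }
  expect_equal(invert_channels(f, matrix(0, 15, 4)),
               matrix(0, 9, 4), tolerance = 1e-14)
  expect_error(invert_channels(f, matrix(0, 14, 2)), "voxels")
})

test_that("noiseless inversion agrees with the pseudo-inverse oracle", {
  set.seed(7)
  b <- default_basis()
  thetas <- runif(45, 0, 180)
  C1 <- design_matrix(b, thetas)
  W_true <- generate_tuning_weights(25, b, seed = 8)
  B1 <- W_true %*% C1
  W <- estimate_weights(B1, C1)
  f <- estimate_noise_filters(B1, C1, W, cov = "identity")
  theta_new <- c(12, 77, 141)
  B2 <- W_true %*% design_matrix(b, theta_new)
  C2 <- invert_channels(f, B2)
  oracle <- solve(crossprod(W), crossprod(W, B2))
  # the pseudo-inverse oracle reproduces the generating channel responses
  expect_equal(unname(oracle), unname(design_matrix(b, theta_new)),
               tolerance = 1e-8)
  # with orthogonalized weight columns the unit-gain filters reduce to the
  # pseudo-inverse and C2 equals c(theta) exactly
  W_orth <- qr.Q(qr(W_true)) %*% diag(runif(9, 0.5, 2))
  B1o <- W_orth %*% C1
  fo <- estimate_noise_filters(B1o, C1, estimate_weights(B1o, C1),
                               cov = "identity")
  B2o <- W_orth %*% design_matrix(b, theta_new)
  expect_equal(unname(invert_channels(fo, B2o)),
               unname(design_matrix(b, theta_new)), tolerance = 1e-8)
})

test_that("aligned reconstructions center the label at zero offset", {
  b <- default_basis()
  thetas <- c(0, 20, 63, 140, 179.5)
  C2 <- design_matrix(b, thetas)  # the ideal responses themselves
  curves <- align_reconstructions(C2, thetas, b)
  grid <- attr(curves, "grid")
  expect_equal(dim(curves), c(5L, 180L))
  # linear interpolation attains its max at a knot, so the aligned peak
  # sits at the offset of the nearest channel center: 0 for on-grid labels
  for (j in seq_along(thetas)) {
    near <- b$centers[which.min(orientation_dist(b$centers, thetas[j]))]
    expected <- round(orientation_diff(near, thetas[j]))
    expect_equal(grid[which.max(curves[j, ])], expected)
  }
})

test_that("alignment is equivariant under label rotation", {
  b <- default_basis()
  set.seed(9)
  resp <- runif(9)
  for (delta in c(20, 40, 60)) {
    # same unaligned curve rotated by one channel spacing, labels shifted
    c_a <- matrix(resp, 9, 1)
    shift <- delta / 20
    c_b <- matrix(resp[((seq_len(9) - 1 - shift) %% 9) + 1], 9, 1)
    cur_a <- align_reconstructions(c_a, 30, b)
    cur_b <- align_reconstructions(c_b, 30 + delta, b)
    expect_equal(cur_a, cur_b, tolerance = 1e-12)
  }
})

test_that("circular interpolation tracks an analytic cosine closely", {
  b <- default_basis()
  resp <- matrix(cos(2 * pi * b$centers / 180), 9, 1)  # cosine sampled at 9 points
  curve <- align_reconstructions(resp, 0, b)
  grid <- attr(curve, "grid")
  analytic <- cos(2 * pi * grid / 180)
  # linear-interpolation error bound h^2 |f''| / 8 with h = 20 degrees
  expect_lt(max(abs(curve[1, ] - analytic)), 20^2 / 8 * (pi / 90)^2 + 1e-6)
})

test_that("the information metric reduces reconstructions as documented", {
  b <- default_basis()
  # uniform profile: equally spaced phasors cancel
  expect_equal(information_metric(rep(3, 9), b$centers), 0, tolerance = 1e-12)
  # delta response at the 0-degree channel: single phasor of mean 1/9
  expect_equal(information_metric(c(1, rep(0, 8)), b$centers), 1 / 9,
               tolerance = 1e-12)
  # response concentrated 90 degrees from center is negative
  expect_lt(information_metric(c(0, 0, 0, 0, 1, 1, 0, 0, 0), b$centers), 0)
  # uniform 180-point curve also gives exactly 0
  expect_equal(information_metric(rep(1, 180), seq(-90, 89)), 0,
               tolerance = 1e-12)
  # matrix input returns one value per row
  m <- rbind(rep(1, 9), c(1, rep(0, 8)))
  expect_equal(information_metric(m, b$centers), c(0, 1 / 9),
               tolerance = 1e-12)
})

test_that("leave-one-block-out decodes every trial exactly once", {
  cfg <- tiny_config()
  sub <- simulate_subject(cfg, 1)
  pat <- extract_delay_patterns(sub$runs, subject_id = 1)
  rec <- lobo_cv(pat, sub$trials, default_basis(), "cued", seed = 1)
  expect_equal(length(rec$R), nrow(sub$trials))
  expect_false(any(is.na(rec$channel_responses)))
  expect_equal(length(rec$folds), cfg$n_blocks)
  expect_equal(sum(vapply(rec$folds, `[[`, integer(1), "n_test")),
               nrow(sub$trials))
  expect_error(lobo_cv(pat, sub$trials, default_basis(), "cued",
                       blocks = rep(1, nrow(sub$trials))), ">= 2 blocks")
})

test_that("noiseless cued decoding peaks at zero offset on every trial", {
  # orthogonal (one-hot) tuning: the identity-covariance filters invert
  # the forward model exactly, so C2 equals c(theta) and every aligned
  # curve peaks at 0
  b <- default_basis()
  cfg <- sim_config(n_subjects = 1, n_blocks = 5L, trials_per_block = 18L,
                    n_voxels = 27L, jitter_range = c(0, 0), snr_cued = 1,
                    noise_sd = 0, lapse_rate = 0, recall_sd = 0, seed = 3)
  tt <- generate_design(cfg, 1)
  W1 <- generate_tuning_weights(27, b, seed = 5, mode = "one_hot")
  pat <- extract_delay_patterns(generate_bold(tt, W1, cfg), zscore = FALSE,
                                subject_id = 1)
  rec <- lobo_cv(pat, tt, b, "cued", cov = "identity")
  expect_equal(unname(rec$channel_responses),
               unname(design_matrix(b, tt$theta_cued)), tolerance = 1e-9)
  peaks <- rec$grid[apply(rec$curves, 1, which.max)]
  expect_true(all(peaks == 0))
  expect_true(all(rec$R > 0))
  # graded correlated tuning: per-channel filters carry crosstalk, so
  # per-trial peaks stay within one channel spacing, the population mean
  # curve still peaks at 0, and information stays positive on every trial
  sub <- noiseless_subject(n_blocks = 5L, trials_per_block = 18L,
                           n_voxels = 27L)
  pat2 <- extract_delay_patterns(sub$runs, zscore = FALSE, subject_id = 1)
  rec2 <- lobo_cv(pat2, sub$trials, default_basis(), "cued", cov = "identity")
  peaks2 <- rec2$grid[apply(rec2$curves, 1, which.max)]
  expect_true(all(abs(peaks2) <= 20))
  expect_equal(rec2$grid[which.max(colMeans(rec2$curves))], 0)
  expect_true(all(rec2$R > 0))
})

test_that("end-to-end decoding is shift equivariant", {
  # rotating every stimulus by one channel spacing rotates the unaligned
  # reconstruction and leaves the aligned curves invariant; exact for
  # crosstalk-free (orthogonal) tuning
  b <- default_basis()
  # block sizes keep every orientation present in each training fold, so
  # the discrete-label design stays full rank
  cfg <- sim_config(n_subjects = 1, n_blocks = 5L, trials_per_block = 18L,
                    n_voxels = 18L, jitter_range = c(0, 0), snr_cued = 1,
                    noise_sd = 0, lapse_rate = 0, recall_sd = 0, seed = 3)
  tt <- generate_design(cfg, 1)
  W1 <- generate_tuning_weights(18, b, seed = 4, mode = "one_hot")
  rot <- tt
  rot$theta_cued <- wrap_orientation(rot$theta_cued + 20)
  pat0 <- generate_delay_patterns(tt, W1, cfg)
  patr <- generate_delay_patterns(rot, W1, cfg)
  rec0 <- lobo_cv(pat0, tt, b, "cued", cov = "identity")
  recr <- lobo_cv(patr, rot, b, "cued", cov = "identity")
  expect_equal(recr$channel_responses,
               rec0$channel_responses[c(9, 1:8), ], tolerance = 1e-8)
  expect_equal(recr$curves, rec0$curves, tolerance = 1e-8)
})

test_that("shuffled-label decoding of pure noise centers on zero information", {
  cfg <- sim_config(n_subjects = 1, n_blocks = 6L, trials_per_block = 18L,
                    n_voxels = 16L, snr_cued = 0, snr_encoding = 0, seed = 99)
  b <- default_basis()
  Rs <- vapply(1:30, function(i) {
    cfg_i <- sim_config(n_subjects = 1, n_blocks = 6L, trials_per_block = 18L,
                        n_voxels = 16L, snr_cued = 0, snr_encoding = 0,
                        seed = 99 + i)
    tt <- generate_design(cfg_i, 1)
    pat <- generate_delay_patterns(tt, matrix(0, 16, 9), cfg_i)
    lobo_cv(pat, tt, b, "shuffled", seed = i)$mean_R
  }, numeric(1))
  expect_lt(abs(mean(Rs)), 3 * sd(Rs) / sqrt(length(Rs)))
})

test_that("random re-blocking partitions trials reproducibly", {
  bl <- random_blocks(180, 18, seed = 4)
  expect_equal(sort(unique(bl)), 1:10)
  expect_true(all(table(bl) == 18))
  expect_identical(bl, random_blocks(180, 18, seed = 4))
  expect_false(identical(bl, random_blocks(180, 18, seed = 5)))
  expect_error(random_blocks(100, 18), "multiple")
})
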