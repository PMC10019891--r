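#' Simulation configuration for the retro-cue orientation task
#'
#' Bundles every parameter of the synthetic experiment: the task design
#' (two sequentially studied orientation gratings drawn from nine base
#' orientations 0-160 degrees in 20-degree steps, with small angular
#' jitter and a minimum separation between items; a retro-cue to one
#' item; a 5-TR retention delay; continuous orientation reproduction),
#' the generative voxel model (tuned weights, signal-to-noise scales for
#' the cued and uncued item during the delay and for both items at
#' encoding, spatially correlated Gaussian noise), and the behavioral
#' response model (wrapped Gaussian recall noise plus a uniform lapse
#' component).
#'
#' Signal scales (`snr_*`) are amplitudes of the tuned signal relative to
#' unit-variance voxel noise before temporal weighting. `trial_gain_sd`
#' adds log-normal trial-to-trial amplitude variability to the delay
#' signal; `precision_coupling` (an exponent `kappa >= 0`) couples recall
#' precision to that amplitude via `sd_t = recall_sd / gain_t^kappa`, so
#' that trials carrying stronger delay-period signal are recalled more
#' precisely. Both default to off (0): the coupling is a simulated
#' hypothesis, not a design fact.
#'
#' @param n_subjects Number of simulated subjects (default 16).
#' @param n_blocks Number of acquisition blocks/runs per subject (default 10).
#' @param trials_per_block Trials in each block (default 18).
#' @param base_orientations Base stimulus orientations in degrees
#'   (default `0, 20, ..., 160`).
#' @param jitter_range Magnitude range of the random angular jitter in
#'   degrees, length-2 (default `c(1, 5)`), applied with a random sign
#'   independently per item.
#' @param min_item_separation Minimum circular orientation distance
#'   between the two items' base orientations, exclusive (default 20).
#' @param n_voxels Voxels per simulated ROI (default 40).
#' @param snr_cued Delay-period signal scale for the cued item (default 0.3).
#' @param snr_uncued Delay-period leakage scale for the uncued item
#'   (default 0).
#' @param snr_encoding Encoding-period scale applied to both items
#'   (default 0.3).
#' @param noise_cov_strength Off-diagonal strength of the spatial noise
#'   covariance (default 0.2).
#' @param noise_sd Voxel noise standard deviation per TR (default 1).
#' @param recall_sd Circular recall noise SD in degrees (default 14.5).
#' @param lapse_rate Probability of a uniform guessing lapse (default 0.03).
#' @param n_delay_trs Delay TRs per trial (default 5).
#' @param n_baseline_trs Pre-stimulus baseline TRs per trial (default 5).
#' @param trial_gain_sd Log-scale SD of the per-trial delay-signal gain
#'   (default 0, i.e. constant gain 1).
#' @param precision_coupling Exponent coupling recall precision to the
#'   trial gain (default 0, no coupling).
#' @param seed Integer seed; every generator output is a pure function of
#'   (config, seed).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 16L, n_blocks = 10L, trials_per_block = 18L,
                       base_orientations = seq(0, 160, by = 20),
                       jitter_range = c(1, 5), min_item_separation = 20,
                       n_voxels = 40L, snr_cued = 0.3, snr_uncued = 0,
                       snr_encoding = 0.3, noise_cov_strength = 0.2,
                       noise_sd = 1, recall_sd = 14.5, lapse_rate = 0.03,
                       n_delay_trs = 5L, n_baseline_trs = 5L,
                       trial_gain_sd = 0, precision_coupling = 0,
                       seed = 1L) {
  .check_scalar(n_subjects, "n_subjects", min = 1)
  .check_scalar(n_blocks, "n_blocks", min = 1)
  .check_scalar(trials_per_block, "trials_per_block", min = 1)
  .check_scalar(min_item_separation, "min_item_separation", min = 0, max = 90)
  .check_scalar(n_voxels, "n_voxels", min = 1)
  for (nm in c("snr_cued", "snr_uncued", "snr_encoding", "noise_cov_strength",
               "noise_sd", "recall_sd", "trial_gain_sd", "precision_coupling")) {
    .check_scalar(get(nm), nm, min = 0)
  }
  .check_scalar(lapse_rate, "lapse_rate", min = 0, max = 1)
  .check_scalar(n_delay_trs, "n_delay_trs", min = 1)
  .check_scalar(n_baseline_trs, "n_baseline_trs", min = 0)
  base_orientations <- as.numeric(base_orientations)
  if (anyDuplicated(base_orientations %% 180)) {
    stop("base orientations must be distinct modulo 180")
  }
  sp <- sort(base_orientations %% 180)
  if (length(sp) > 1 && length(unique(round(diff(sp), 9))) != 1L) {
    stop("base orientations must be evenly spaced")
  }
  if (!is.numeric(jitter_range) || length(jitter_range) != 2L ||
      any(jitter_range < 0) || jitter_range[1] > jitter_range[2]) {
    stop("jitter_range must be a nondecreasing pair of nonnegative degrees")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_blocks = as.integer(n_blocks),
         trials_per_block = as.integer(trials_per_block),
         base_orientations = base_orientations, jitter_range = jitter_range,
         min_item_separation = min_item_separation,
         n_voxels = as.integer(n_voxels), snr_cued = snr_cued,
         snr_uncued = snr_uncued, snr_encoding = snr_encoding,
         noise_cov_strength = noise_cov_strength, noise_sd = noise_sd,
         recall_sd = recall_sd, lapse_rate = lapse_rate,
         n_delay_trs = as.integer(n_delay_trs),
         n_baseline_trs = as.integer(n_baseline_trs),
         trial_gain_sd = trial_gain_sd,
         precision_coupling = precision_coupling,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d subjects, %d blocks x %d trials, %d voxels, seed %d\n",
    x$n_subjects, x$n_blocks, x$trials_per_block, x$n_voxels, x$seed))
  cat(sprintf("  snr cued/uncued/encoding: %g/%g/%g; recall_sd %g, lapse %g\n",
              x$snr_cued, x$snr_uncued, x$snr_encoding, x$recall_sd,
              x$lapse_rate))
  invisible(x)
}

#' Generate a trial table for one subject
#'
#' Draws, per trial, two base orientations from the configured set with a
#' circular separation strictly greater than `min_item_separation`,
#' jitters each by a uniform magnitude in `jitter_range` with random sign,
#' and assigns the retro-cue (balanced within each block). Per-trial
#' delay-signal gains are drawn log-normally when `trial_gain_sd > 0`.
#'
#' @param config A [sim_config()].
#' @param subject_id Integer subject index; offsets the seed so subjects
#'   are independent but jointly reproducible.
#' @return A `data.frame` with one row per trial: `trial_id`, `block`,
#'   `base_item1`, `base_item2`, `theta_item1`, `theta_item2`, `cue`,
#'   `theta_cued`, `theta_uncued`, `gain`.
#' @export
generate_design <- function(config, subject_id = 1L) {
  stopifnot(inherits(config, "sim_config"))
  bases <- config$base_orientations
  sep_ok <- outer(bases, bases, orientation_dist) > config$min_item_separation
  if (!any(sep_ok)) {
    stop("infeasible design: no base-orientation pair exceeds min_item_separation")
  }
  set.seed(.substream_seed(config$seed, subject_id * 8L + 1L))
  n <- config$n_blocks * config$trials_per_block
  b1 <- sample(seq_along(bases), n, replace = TRUE)
  b2 <- vapply(b1, function(i) {
    ok <- which(sep_ok[i, ])
    if (length(ok) == 0L) stop("infeasible design for base orientation ", bases[i])
    ok[sample.int(length(ok), 1L)]
  }, integer(1))
  jit <- function() {
    sign <- sample(c(-1, 1), n, replace = TRUE)
    sign * stats::runif(n, config$jitter_range[1], config$jitter_range[2])
  }
  theta1 <- wrap_orientation(bases[b1] + jit())
  theta2 <- wrap_orientation(bases[b2] + jit())
  # balanced retro-cue within block
  cue <- as.vector(vapply(seq_len(config$n_blocks), function(b) {
    sample(rep(c(1L, 2L), length.out = config$trials_per_block))
  }, integer(config$trials_per_block)))
  gain <- if (config$trial_gain_sd > 0) {
    exp(stats::rnorm(n, 0, config$trial_gain_sd))
  } else rep(1, n)
  data.frame(
    subject_id = as.integer(subject_id),
    trial_id = seq_len(n),
    block = rep(seq_len(config$n_blocks), each = config$trials_per_block),
    base_item1 = bases[b1], base_item2 = bases[b2],
    theta_item1 = theta1, theta_item2 = theta2,
    cue = cue,
    theta_cued = ifelse(cue == 1L, theta1, theta2),
    theta_uncued = ifelse(cue == 1L, theta2, theta1),
    gain = gain
  )
}

#' Generate ground-truth voxel tuning weights
#'
#' Each voxel is assigned a preferred channel; its loading profile across
#' channels is a rectified-cosine bump around that preference, scaled by a
#' random per-voxel gain, plus a small nonnegative uniform offset. Every
#' channel is guaranteed at least one voxel that prefers it (when
#' `n_voxels >= n_channels`), giving heterogeneous but complete coverage
#' of orientation space.
#'
#' @param n_voxels Number of voxels.
#' @param basis A [channel_basis()].
#' @param seed Integer seed.
#' @param mode `"tuned"` (default) for graded circular tuning;
#'   `"one_hot"` for the degenerate case where each voxel loads on
#'   exactly one channel.
#' @return Nonnegative numeric matrix, `n_voxels` x `n_channels`.
#' @export
generate_tuning_weights <- function(n_voxels, basis, seed = 1L,
                                    mode = c("tuned", "one_hot")) {
  mode <- match.arg(mode)
  .check_scalar(n_voxels, "n_voxels", min = 1)
  stopifnot(inherits(basis, "channel_basis"))
  set.seed(as.integer(seed))
  k <- basis$n_channels
  pref <- c(seq_len(min(k, n_voxels)),
            if (n_voxels > k) sample.int(k, n_voxels - k, replace = TRUE))
  pref <- sample(pref)  # shuffle which voxel gets which guaranteed channel
  if (mode == "one_hot") {
    W <- matrix(0, n_voxels, k)
    W[cbind(seq_len(n_voxels), pref)] <- 1
    return(W)
  }
  prof <- .channel_resp_matrix(
    channel_basis(k, basis$centers, exponent = 2, space = basis$space),
    basis$centers)
  W <- prof[pref, , drop = FALSE] * stats::runif(n_voxels, 0.5, 1.5) +
    matrix(stats::runif(n_voxels * k, 0, 0.1), n_voxels, k)
  dimnames(W) <- NULL
  W
}

# internal: subject-level spatial noise covariance and its Cholesky factor
.noise_chol <- function(config, subject_id) {
  m <- config$n_voxels
  if (config$noise_sd == 0 || config$noise_cov_strength == 0) {
    return(diag(config$noise_sd, m))
  }
  set.seed(.substream_seed(config$seed, subject_id * 8L + 2L))
  A <- matrix(stats::rnorm(m * m), m, m)
  sigma <- config$noise_sd^2 *
    (diag(m) + config$noise_cov_strength * tcrossprod(A) / m)
  t(chol(sigma))
}

#' Spatial noise covariance implied by a configuration
#'
#' The model is `noise_sd^2 * (I + noise_cov_strength * A A' / m)` with
#' `A` a fixed standard-normal matrix per subject: full rank, symmetric
#' positive definite, controllable off-diagonal strength.
#'
#' @inheritParams generate_design
#' @return The `n_voxels` x `n_voxels` covariance matrix.
#' @export
noise_covariance <- function(config, subject_id = 1L) {
  L <- .noise_chol(config, subject_id)
  tcrossprod(L)
}

#' Generate run-wise voxel time series for one subject
#'
#' Lays each trial out on a fixed TR grid (baseline TRs, one encoding TR,
#' one cue TR, `n_delay_trs` delay TRs, one response TR) and adds the
#' tuned signal: both items at `snr_encoding` during encoding; the cued
#' item at `snr_cued` (times the trial gain) plus the uncued item at
#' `snr_uncued` during every delay TR; spatially correlated Gaussian
#' noise everywhere. No hemodynamic convolution is applied: the analysis
#' consumes raw delay TRs.
#'
#' @param trials A trial table from [generate_design()].
#' @param weights Voxel tuning weights (`n_voxels` x `n_channels`).
#' @param config A [sim_config()].
#' @param basis A [channel_basis()]; defaults to 9 channels at the base
#'   orientations.
#' @return A list of `bold_run` objects, one per block, each with a
#'   TRs x voxels `data` matrix and an `event_map` giving per-trial TR
#'   indices for `baseline`, `encoding`, `cue`, `delay` and `response`.
#' @export
generate_bold <- function(trials, weights, config,
                          basis = channel_basis(
                            length(config$base_orientations),
                            config$base_orientations)) {
  stopifnot(inherits(config, "sim_config"))
  if (ncol(weights) != basis$n_channels) {
    stop("weights have ", ncol(weights), " channels but basis has ",
         basis$n_channels)
  }
  if (nrow(weights) != config$n_voxels) {
    stop("weights have ", nrow(weights), " voxels but config expects ",
         config$n_voxels)
  }
  subject_id <- trials$subject_id[1]
  set.seed(.substream_seed(config$seed, subject_id * 8L + 3L))
  L <- .noise_chol(config, subject_id)
  m <- config$n_voxels
  nb <- config$n_baseline_trs
  nd <- config$n_delay_trs
  trs_per_trial <- nb + 1L + 1L + nd + 1L
  lapply(seq_len(config$n_blocks), function(b) {
    tt <- trials[trials$block == b, , drop = FALSE]
    ntr <- nrow(tt) * trs_per_trial
    noise <- t(L %*% matrix(stats::rnorm(ntr * m), m, ntr))
    data <- noise
    event_map <- vector("list", nrow(tt))
    for (j in seq_len(nrow(tt))) {
      off <- (j - 1L) * trs_per_trial
      ev <- list(
        baseline = if (nb > 0) off + seq_len(nb) else integer(0),
        encoding = off + nb + 1L,
        cue      = off + nb + 2L,
        delay    = off + nb + 2L + seq_len(nd),
        response = off + nb + 2L + nd + 1L
      )
      enc <- config$snr_encoding *
        (channel_response(basis, tt$theta_item1[j]) +
         channel_response(basis, tt$theta_item2[j]))
      data[ev$encoding, ] <- data[ev$encoding, ] + drop(weights %*% enc)
      del <- tt$gain[j] * config$snr_cued *
        channel_response(basis, tt$theta_cued[j]) +
        config$snr_uncued * channel_response(basis, tt$theta_uncued[j])
      sig <- drop(weights %*% del)
      data[ev$delay, ] <- data[ev$delay, ] + rep(sig, each = nd)
      ev$trial_id <- tt$trial_id[j]
      event_map[[j]] <- ev
    }
    bold_run(data, event_map, run_id = b)
  })
}

#' Construct a run-wise time-series container
#'
#' @param data TRs x voxels numeric matrix; finite values only.
#' @param event_map List with one element per trial giving TR indices for
#'   the trial's epochs (`baseline`, `encoding`, `cue`, `delay`,
#'   `response`) and its `trial_id`.
#' @param run_id Integer run index.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, event_map, run_id = 1L) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("bold_run data must be finite")
  for (ev in event_map) {
    idx <- unlist(ev[setdiff(names(ev), "trial_id")])
    if (any(idx < 1 | idx > nrow(data))) {
      stop("event map indexes TRs outside the run")
    }
  }
  structure(list(data = data, event_map = event_map,
                 run_id = as.integer(run_id)),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("bold_run %d: %d TRs x %d voxels, %d trials\n", x$run_id,
              nrow(x$data), ncol(x$data), length(x$event_map)))
  invisible(x)
}

#' Generate behavioral recall responses
#'
#' With probability `1 - lapse_rate` the report is the cued orientation
#' plus wrapped Gaussian noise (SD `recall_sd`, shrunk by the trial gain
#' when `precision_coupling > 0`); with probability `lapse_rate` it is
#' uniform on `[0, 180)`. `lapse_flag` records which branch generated
#' each trial (available in simulation only).
#'
#' @inheritParams generate_bold
#' @return The trial table with `reported` and `lapse_flag` columns added.
#' @export
generate_behavior <- function(trials, config) {
  stopifnot(inherits(config, "sim_config"), "theta_cued" %in% names(trials))
  subject_id <- trials$subject_id[1]
  set.seed(.substream_seed(config$seed, subject_id * 8L + 4L))
  n <- nrow(trials)
  lapse <- stats::runif(n) < config$lapse_rate
  sd_t <- config$recall_sd / trials$gain^config$precision_coupling
  noise <- stats::rnorm(n, 0, sd_t)
  reported <- wrap_orientation(trials$theta_cued + noise)
  reported[lapse] <- stats::runif(sum(lapse), 0, 180)
  trials$reported <- reported
  trials$lapse_flag <- lapse
  trials
}

#' Generate delay-period patterns directly (run-free shortcut)
#'
#' Produces the trials x voxels delay pattern a noiseless TR grid plus
#' TENT weighting would yield, with noise at the temporally weighted
#' level `noise_sd * sqrt(sum(w^2)) / sum(w)` for the default weights
#' `(0, 1, 2, 1, 0)`. Useful for large replicate simulations (e.g. null
#' calibration) where generating full time series is wasteful.
#'
#' @inheritParams generate_bold
#' @param tent_weights Temporal weights whose noise-reduction factor is
#'   applied (default `c(0, 1, 2, 1, 0)`).
#' @return A `delay_pattern` matrix (trials x voxels).
#' @export
generate_delay_patterns <- function(trials, weights, config,
                                    basis = channel_basis(
                                      length(config$base_orientations),
                                      config$base_orientations),
                                    tent_weights = c(0, 1, 2, 1, 0)) {
  stopifnot(inherits(config, "sim_config"))
  subject_id <- trials$subject_id[1]
  set.seed(.substream_seed(config$seed, subject_id * 8L + 5L))
  L <- .noise_chol(config, subject_id)
  m <- config$n_voxels
  n <- nrow(trials)
  shrink <- sqrt(sum(tent_weights^2)) / sum(tent_weights)
  noise <- shrink * t(L %*% matrix(stats::rnorm(n * m), m, n))
  Ccued <- .channel_resp_matrix(basis, trials$theta_cued)
  Cunc <- .channel_resp_matrix(basis, trials$theta_uncued)
  signal <- (trials$gain * config$snr_cued) * (Ccued %*% t(weights)) +
    config$snr_uncued * (Cunc %*% t(weights))
  delay_pattern(signal + noise, subject_id = subject_id)
}

#' Simulate one subject end to end
#'
#' Convenience wrapper: design, behavior, ground-truth tuning weights and
#' run-wise time series for a single subject.
#'
#' @inheritParams generate_design
#' @param basis A [channel_basis()].
#' @param runs Logical; generate the TR-level time series (default TRUE).
#'   When FALSE only design, behavior and weights are returned.
#' @return A list with `trials`, `weights` and (optionally) `runs`.
#' @export
simulate_subject <- function(config, subject_id = 1L,
                             basis = channel_basis(
                               length(config$base_orientations),
                               config$base_orientations),
                             runs = TRUE) {
  trials <- generate_design(config, subject_id)
  trials <- generate_behavior(trials, config)
  weights <- generate_tuning_weights(
    config$n_voxels, basis,
    seed = .substream_seed(config$seed, subject_id * 8L + 6L))
  out <- list(trials = trials, weights = weights, subject_id = subject_id)
  if (runs) out$runs <- generate_bold(trials, weights, config, basis)
  out
}
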