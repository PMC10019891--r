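#' Estimate encoding weights by ordinary least squares
#'
#' Solves the forward model `B1 = W C1 + N` for the weight matrix
#' `W = B1 C1' (C1 C1')^-1`, i.e. an independent least-squares fit per
#' voxel. If the channel design is rank deficient the Moore-Penrose
#' pseudo-inverse is used instead, with a warning.
#'
#' @param B1 Training patterns, voxels x trials.
#' @param C1 Channel design, channels x trials (see [design_matrix()]).
#' @return Weight matrix `W`, voxels x channels.
#' @export
estimate_weights <- function(B1, C1) {
  B1 <- as.matrix(B1); C1 <- as.matrix(C1)
  if (ncol(B1) != ncol(C1)) {
    stop("B1 and C1 must have the same number of trials (columns)")
  }
  if (ncol(C1) < nrow(C1)) {
    warning("fewer training trials than channels; design is rank deficient")
  }
  G <- tcrossprod(C1)
  Ginv <- tryCatch(
    chol2inv(chol(G)),
    error = function(e) {
      warning("channel design C1 C1' is singular; using pseudo-inverse")
      s <- svd(G)
      pos <- s$d > max(s$d) * ncol(G) * .Machine$double.eps
      s$v[, pos, drop = FALSE] %*%
        (t(s$u[, pos, drop = FALSE]) / s$d[pos])
    })
  B1 %*% t(C1) %*% Ginv
}

# internal: Ledoit-Wolf-style analytic shrinkage of an uncentered
# residual covariance toward a scaled identity target.
# X: voxels x trials residual matrix. Returns list(sigma, intensity).
.shrink_covariance <- function(X, delta = 1e-6) {
  m <- nrow(X); n <- ncol(X)
  S <- tcrossprod(X) / (n - 1)
  mu <- sum(diag(S)) / m
  d2 <- sum((S - diag(mu, m))^2)
  if (!is.finite(d2) || d2 <= .Machine$double.eps * m) {
    if (mu <= .Machine$double.eps) {
      warning("all-zero residuals; falling back to sigma = ", delta, " * I")
      return(list(sigma = diag(delta, m), intensity = 1))
    }
    return(list(sigma = S, intensity = 0))
  }
  # sum_t || x_t x_t' - S ||_F^2 expanded: sum ||x_t||^4 - (n - 2) ||S||^2
  # (using sum_t x_t x_t' = (n - 1) S)
  norms2 <- colSums(X^2)
  b2 <- (sum(norms2^2) - (n - 2) * sum(S^2)) / n^2
  intensity <- min(1, max(0, b2 / d2))
  sigma <- intensity * diag(mu, m) + (1 - intensity) * S
  list(sigma = sigma, intensity = intensity)
}

#' Estimate per-channel noise covariances and optimal filters
#'
#' For each channel `i`, the training residual `eps_i = B1 - W_i C1_i`
#' (the rank-one prediction from channel `i` alone) yields an uncentered
#' covariance `eps_i eps_i' / (n1 - 1)`, regularized by analytic
#' Ledoit-Wolf-style shrinkage toward a scaled identity target. The
#' optimal filter for channel `i` is
#' `V_i = Sigma_i^-1 W_i / (W_i' Sigma_i^-1 W_i)`, which has unit gain on
#' its own channel (`V_i' W_i = 1`) while down-weighting directions of
#' high noise covariance.
#'
#' @param B1 Training patterns, voxels x trials.
#' @param C1 Channel design, channels x trials.
#' @param W Weights from [estimate_weights()] on the same training data.
#' @param cov `"shrinkage"` (default) for the regularized noise
#'   covariance path; `"identity"` to ignore noise covariance, giving
#'   `V_i = W_i / (W_i' W_i)`.
#' @param delta Ridge used if a regularized covariance is still singular.
#' @return An object of class `iem_filters`: `W`, `V` (voxels x
#'   channels), per-channel `shrinkage` intensities, `sigma_inv` (list of
#'   inverse covariances, shrinkage path only) and `n_train`.
#' @export
estimate_noise_filters <- function(B1, C1, W = estimate_weights(B1, C1),
                                   cov = c("shrinkage", "identity"),
                                   delta = 1e-6) {
  cov <- match.arg(cov)
  B1 <- as.matrix(B1); C1 <- as.matrix(C1); W <- as.matrix(W)
  k <- nrow(C1); m <- nrow(B1); n1 <- ncol(B1)
  stopifnot(ncol(W) == k, nrow(W) == m)
  V <- matrix(0, m, k)
  shrinkage <- rep(NA_real_, k)
  sigma_inv <- vector("list", k)
  for (i in seq_len(k)) {
    wi <- W[, i]
    if (cov == "identity") {
      denom <- sum(wi^2)
      if (denom <= .Machine$double.eps) stop("channel ", i, " has zero weights")
      V[, i] <- wi / denom
      next
    }
    eps <- B1 - wi %*% C1[i, , drop = FALSE]
    sh <- .shrink_covariance(eps, delta = delta)
    shrinkage[i] <- sh$intensity
    si <- tryCatch(chol2inv(chol(sh$sigma)), error = function(e) {
      warning("regularized covariance for channel ", i,
              " is singular; adding ridge ", delta)
      chol2inv(chol(sh$sigma + diag(delta, m)))
    })
    sigma_inv[[i]] <- si
    siw <- si %*% wi
    V[, i] <- siw / drop(crossprod(wi, siw))
  }
  structure(list(W = W, V = V, shrinkage = shrinkage,
                 sigma_inv = if (cov == "shrinkage") sigma_inv else NULL,
                 cov = cov, n_train = n1),
            class = "iem_filters")
}

#' @export
print.iem_filters <- function(x, ...) {
  cat(sprintf("iem_filters: %d voxels x %d channels (%s covariance), n_train %d\n",
              nrow(x$W), ncol(x$W), x$cov, x$n_train))
  if (x$cov == "shrinkage") {
    cat("shrinkage:", paste(signif(x$shrinkage, 3), collapse = " "), "\n")
  }
  invisible(x)
}

#' Invert the encoding model on held-out patterns
#'
#' Applies the optimal filters to test patterns: `C2 = V' B2`. No
#' renormalization is applied.
#'
#' @param filters An [estimate_noise_filters()] result.
#' @param B2 Test patterns, voxels x trials.
#' @return Reconstructed channel responses, channels x trials.
#' @export
invert_channels <- function(filters, B2) {
  stopifnot(inherits(filters, "iem_filters"))
  B2 <- as.matrix(B2)
  if (nrow(B2) != nrow(filters$V)) {
    stop("B2 has ", nrow(B2), " voxels but filters were trained on ",
         nrow(filters$V))
  }
  crossprod(filters$V, B2)
}

#' Align channel-response reconstructions to a common center
#'
#' Places each trial's k channel responses at the channel centers,
#' interpolates circularly (linear on the wrapped domain) to a 1-degree,
#' 180-point grid, and rotates the curve so the trial's orientation label
#' sits at 0 degrees. The returned grid spans offsets -90..89 degrees.
#'
#' @param C2 Channel responses, channels x trials (from
#'   [invert_channels()]).
#' @param labels Orientation label in degrees for each trial (cued,
#'   uncued, or shuffled, depending on the condition).
#' @param basis The [channel_basis()] the model was trained with.
#' @return A trials x 180 matrix of aligned curves with attribute `grid`
#'   (offsets in degrees, -90..89).
#' @export
align_reconstructions <- function(C2, labels, basis) {
  C2 <- as.matrix(C2)
  stopifnot(inherits(basis, "channel_basis"))
  if (ncol(C2) != length(labels)) {
    stop("need one label per test trial")
  }
  sp <- basis$space
  ord <- order(basis$centers %% sp)
  cx <- (basis$centers %% sp)[ord]
  grid <- seq(-sp / 2, sp / 2 - 1, by = 1)
  knots <- c(cx, cx[1] + sp)  # wrap the first channel to close the circle
  curves <- vapply(seq_len(ncol(C2)), function(j) {
    y <- C2[ord, j]
    # absolute orientations to evaluate, mapped into [cx[1], cx[1] + sp)
    ang <- (labels[j] + grid - cx[1]) %% sp + cx[1]
    stats::approx(knots, c(y, y[1]), xout = ang, method = "linear")$y
  }, numeric(length(grid)))
  out <- t(curves)
  attr(out, "grid") <- grid
  out
}

#' Scalar information metric of a reconstruction
#'
#' Treats the responses as phasors at orientation-doubled angles,
#' averages them, and projects the mean phasor onto the 0-degree
#' direction: `R = Re(mean(resp * exp(2i * angle)))` with angles in
#' radians. After alignment the target orientation sits at angle 0, so R
#' is positive for correctly centered reconstructions, 0 for a uniform
#' (information-free) profile, and negative for profiles concentrated at
#' the orthogonal orientation.
#'
#' @param responses Numeric vector of responses (k channels or a
#'   180-point curve), or a matrix with one row per trial.
#' @param angles Angles in degrees at which the responses sit, relative
#'   to the alignment center (e.g. `centers - label`, or the curve grid).
#' @return R, a scalar (or one value per row of a matrix input).
#' @export
information_metric <- function(responses, angles) {
  phasor <- exp(2i * angles * pi / 180)
  if (is.matrix(responses)) {
    stopifnot(ncol(responses) == length(angles))
    drop(Re(responses %*% phasor)) / length(angles)
  } else {
    stopifnot(length(responses) == length(angles))
    Re(mean(responses * phasor))
  }
}

#' Leave-one-block-out inverted encoding analysis
#'
#' For each block, trains the encoding model (weights, then
#' noise-covariance optimal filters) on all other blocks and reconstructs
#' channel responses for the held-out block, so every trial is decoded
#' exactly once. Labels follow the condition: the cued item's
#' orientation, the uncued item's, or a seeded within-subject shuffle of
#' the cued labels. Returns aligned curves, per-trial information R, and
#' condition-level summaries.
#'
#' @param patterns A [delay_pattern()] (trials x voxels), rows in trial
#'   order.
#' @param trials The matching trial table (needs `block`, `theta_cued`,
#'   `theta_uncued`).
#' @param basis A [channel_basis()].
#' @param condition `"cued"`, `"uncued"`, or `"shuffled"`.
#' @param blocks Optional block assignment overriding `trials$block`
#'   (e.g. from [random_blocks()] for the trialwise re-blocked variant).
#' @param cov Covariance path passed to [estimate_noise_filters()].
#' @param seed Seed for the shuffled condition.
#' @return An object of class `iem_reconstruction`: `curves` (trials x
#'   180 aligned), `grid`, `R` (per trial), `mean_R` (trial-averaged),
#'   `R_of_mean_curve`, `channel_responses` (k x trials, unaligned),
#'   `labels`, `condition`, `folds`.
#' @export
lobo_cv <- function(patterns, trials, basis,
                    condition = c("cued", "uncued", "shuffled"),
                    blocks = NULL, cov = c("shrinkage", "identity"),
                    seed = 1L) {
  condition <- match.arg(condition)
  cov <- match.arg(cov)
  B <- t(as.matrix(patterns))  # voxels x trials
  n <- ncol(B)
  stopifnot(nrow(trials) == n)
  if (is.null(blocks)) blocks <- trials$block
  ublocks <- unique(blocks)
  if (length(ublocks) < 2L) stop("lobo_cv() needs >= 2 blocks")
  labels <- switch(condition,
    cued = trials$theta_cued,
    uncued = trials$theta_uncued,
    shuffled = {
      set.seed(as.integer(seed))
      sample(trials$theta_cued)
    })
  C_all <- design_matrix(basis, labels)
  C2 <- matrix(NA_real_, basis$n_channels, n)
  folds <- vector("list", length(ublocks))
  for (f in seq_along(ublocks)) {
    test <- blocks == ublocks[f]
    train <- !test
    C1_train <- C_all[, train, drop = FALSE]
    if (length(unique(round(labels[train], 6))) < 2L) {
      warning("fold ", f, ": training labels lack variety")
    }
    W <- estimate_weights(B[, train, drop = FALSE], C1_train)
    filt <- estimate_noise_filters(B[, train, drop = FALSE], C1_train, W,
                                   cov = cov)
    C2[, test] <- invert_channels(filt, B[, test, drop = FALSE])
    folds[[f]] <- list(block = ublocks[f], n_train = sum(train),
                       n_test = sum(test),
                       shrinkage = filt$shrinkage)
  }
  curves <- align_reconstructions(C2, labels, basis)
  grid <- attr(curves, "grid")
  # per-trial R straight from the k channel responses at aligned angles
  R <- vapply(seq_len(n), function(j) {
    information_metric(C2[, j], basis$centers - labels[j])
  }, numeric(1))
  structure(list(curves = curves, grid = grid, R = R, mean_R = mean(R),
                 R_of_mean_curve = information_metric(colMeans(curves), grid),
                 channel_responses = C2, labels = labels,
                 condition = condition, folds = folds,
                 subject_id = attr(patterns, "subject_id")),
            class = "iem_reconstruction")
}

#' @export
print.iem_reconstruction <- function(x, ...) {
  cat(sprintf("iem_reconstruction (%s): %d trials, mean R = %.4f\n",
              x$condition, length(x$R), x$mean_R))
  invisible(x)
}

#' Random re-blocking of trials
#'
#' Seeded permutation of trials into consecutive blocks of a fixed size,
#' used for the error-linked analysis where decoding must be agnostic to
#' the acquisition blocks.
#'
#' @param n_trials Number of trials.
#' @param block_size Trials per block (default 18).
#' @param seed Integer seed.
#' @return Integer block labels of length `n_trials`.
#' @export
random_blocks <- function(n_trials, block_size = 18L, seed = 1L) {
  if (n_trials %% block_size != 0) {
    stop("n_trials must be a multiple of block_size")
  }
  set.seed(as.integer(seed))
  blocks <- rep(seq_len(n_trials %/% block_size), each = block_size)
  blocks[sample.int(n_trials)]
}
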