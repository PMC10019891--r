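#' Trial-pair cosine similarity of neural patterns
#'
#' `S(B_i, B_j) = B_i . B_j / (||B_i|| ||B_j||)` for every pair of
#' trials' voxel patterns. Zero-norm rows yield 0 entries with a warning.
#'
#' @param patterns Trials x voxels matrix (e.g. a [delay_pattern()]).
#' @return A symmetric trials x trials matrix with unit diagonal for
#'   nonzero patterns.
#' @export
neural_similarity <- function(patterns) {
  X <- as.matrix(patterns)
  norms <- sqrt(rowSums(X^2))
  zero <- norms <= .Machine$double.eps
  if (any(zero)) {
    warning(sum(zero), " zero-norm pattern row(s); similarities set to 0")
    norms[zero] <- 1
  }
  S <- tcrossprod(X / norms)
  S[zero, ] <- 0
  S[, zero] <- 0
  # clamp numerical overshoot
  S[S > 1] <- 1; S[S < -1] <- -1
  S
}

#' Trial-pair stimulus similarity
#'
#' 180 minus the circular orientation distance between the trial labels,
#' with the distance taken on the 180-degree orientation metric (maximum
#' 90). Entries therefore lie in `[90, 180]`; identical orientations
#' score 180.
#'
#' @param thetas Orientation labels in degrees, one per trial.
#' @return A symmetric trials x trials matrix.
#' @export
stimulus_similarity <- function(thetas) {
  thetas <- as.numeric(thetas)
  180 - outer(thetas, thetas, orientation_dist)
}

#' Rank-order association between similarity matrices
#'
#' Spearman rank correlation (average ranks for ties) between the lower
#' triangles (diagonal excluded) of a neural and a stimulus similarity
#' matrix, plus the Fisher z transform `atanh(rho)` with `|rho|` clipped
#' at `1 - 1e-7` to keep z finite.
#'
#' @param neural,stimulus Matching square similarity matrices.
#' @return An object of class `similarity_association`: `rho`,
#'   `fisher_z`, `n_pairs`.
#' @export
similarity_association <- function(neural, stimulus) {
  neural <- as.matrix(neural); stimulus <- as.matrix(stimulus)
  if (!all(dim(neural) == dim(stimulus))) {
    stop("similarity matrices must have matching dimensions")
  }
  lt <- lower.tri(neural)
  a <- neural[lt]; b <- stimulus[lt]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant similarity vector; association undefined")
    return(structure(list(rho = NA_real_, fisher_z = NA_real_,
                          n_pairs = sum(lt)),
                     class = "similarity_association"))
  }
  rho <- stats::cor(a, b, method = "spearman")
  clipped <- sign(rho) * min(abs(rho), 1 - 1e-7)
  structure(list(rho = rho, fisher_z = atanh(clipped), n_pairs = sum(lt)),
            class = "similarity_association")
}

#' @export
print.similarity_association <- function(x, ...) {
  cat(sprintf("similarity_association: rho = %.4f, Fisher z = %.4f (%d pairs)\n",
              x$rho, x$fisher_z, x$n_pairs))
  invisible(x)
}

#' Second-order similarity between two regions
#'
#' Rank correlation between the lower triangles of two regions'
#' trial-pair neural-similarity matrices (a similarity-of-similarities).
#' Passing patterns extracted from different epochs (pre-stimulus
#' baseline vs. delay) supports the baseline-vs-delay contrast.
#'
#' @param patterns_a,patterns_b Trials x voxels matrices over the same
#'   trials.
#' @return Spearman rho between the regions' similarity structures.
#' @export
cross_region_similarity <- function(patterns_a, patterns_b) {
  if (nrow(patterns_a) != nrow(patterns_b)) {
    stop("regions must cover the same trials")
  }
  sa <- neural_similarity(patterns_a)
  sb <- neural_similarity(patterns_b)
  lt <- lower.tri(sa)
  stats::cor(sa[lt], sb[lt], method = "spearman")
}
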