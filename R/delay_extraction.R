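#' Construct a delay-pattern container
#'
#' A trials x voxels matrix of per-trial activity for one ROI and
#' subject, with provenance attributes.
#'
#' @param data Trials x voxels numeric matrix.
#' @param subject_id Subject index.
#' @param roi_id ROI label.
#' @param peak_shift Signed TR offset of the temporal weighting window.
#' @return A `delay_pattern` object (a matrix with attributes).
#' @export
delay_pattern <- function(data, subject_id = NA_integer_, roi_id = "roi",
                          peak_shift = 0L) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("delay_pattern data must be finite")
  structure(data, subject_id = subject_id, roi_id = roi_id,
            peak_shift = peak_shift,
            class = c("delay_pattern", class(data)))
}

#' Z-score a run's time series within run
#'
#' Per voxel, subtracts the run mean and divides by the run SD across all
#' TRs of the run, so each voxel has mean 0 and SD 1 within the run.
#' The population SD convention (divide by n) is the default;
#' `ddof = 1` selects the sample convention. Zero-variance voxels are
#' set to 0 with a warning.
#'
#' @param run A [bold_run()].
#' @param ddof Degrees-of-freedom correction for the SD (0 = population,
#'   the default; 1 = sample).
#' @return The run with standardized `data`.
#' @export
zscore_within_run <- function(run, ddof = 0) {
  stopifnot(inherits(run, "bold_run"))
  x <- run$data
  n <- nrow(x)
  if (n < 2L) stop("zscore_within_run() needs >= 2 TRs")
  mu <- colMeans(x)
  centered <- sweep(x, 2L, mu)
  sdv <- sqrt(colSums(centered^2) / (n - ddof))
  zero <- sdv <= .Machine$double.eps * n
  if (any(zero)) {
    warning(sum(zero), " zero-variance voxel(s) set to 0 in run ", run$run_id)
    sdv[zero] <- 1
    centered[, zero] <- 0
  }
  run$data <- sweep(centered, 2L, sdv, "/")
  run
}

#' TENT-weighted per-trial pattern from a run
#'
#' Collapses each trial's delay (or other epoch) TRs into a single
#' voxel pattern using a normalized weighted mean with triangular
#' ("TENT") weights, by default `(0, 1, 2, 1, 0)` across the 5 delay
#' TRs — equivalent to averaging the middle 3 TRs with the midpoint
#' double-weighted. `peak_shift` slides the window across time for the
#' time-varying variant.
#'
#' @param run A [bold_run()], typically after [zscore_within_run()].
#' @param weights Temporal weights; length must match the epoch window.
#' @param peak_shift Signed TR offset applied to the window (default 0).
#' @param epoch Which event-map epoch to weight (default `"delay"`;
#'   `"baseline"` gives pre-stimulus patterns for control analyses).
#' @return A matrix with one row per trial in the run (trials x voxels),
#'   plus a `trial_id` attribute.
#' @export
tent_delay_pattern <- function(run, weights = c(0, 1, 2, 1, 0),
                               peak_shift = 0L, epoch = "delay") {
  stopifnot(inherits(run, "bold_run"))
  weights <- as.numeric(weights)
  if (sum(weights) <= 0) stop("weights must have positive sum")
  w <- weights / sum(weights)
  n_tr <- nrow(run$data)
  rows <- lapply(run$event_map, function(ev) {
    win <- ev[[epoch]]
    if (is.null(win)) stop("epoch '", epoch, "' absent from event map")
    if (length(win) != length(weights)) {
      stop(sprintf("trial %s: epoch '%s' spans %d TRs but %d weights given",
                   ev$trial_id, epoch, length(win), length(weights)))
    }
    win <- win + as.integer(peak_shift)
    if (any(win < 1L | win > n_tr)) {
      stop(sprintf("trial %s: shifted window [%d, %d] leaves the run",
                   ev$trial_id, min(win), max(win)))
    }
    drop(crossprod(run$data[win, , drop = FALSE], w))
  })
  out <- do.call(rbind, rows)
  attr(out, "trial_id") <- vapply(run$event_map, `[[`, integer(1), "trial_id")
  out
}

#' Extract delay patterns for all runs of a subject
#'
#' Applies within-run z-scoring followed by TENT weighting to every run
#' and stacks the per-trial rows in trial order.
#'
#' @param runs List of [bold_run()] objects.
#' @param weights,peak_shift,epoch Passed to [tent_delay_pattern()].
#' @param zscore Logical; standardize within run first (default TRUE).
#' @param ddof Passed to [zscore_within_run()].
#' @param subject_id,roi_id Provenance labels for the result.
#' @return A [delay_pattern()] with rows ordered by trial id.
#' @export
extract_delay_patterns <- function(runs, weights = c(0, 1, 2, 1, 0),
                                   peak_shift = 0L, epoch = "delay",
                                   zscore = TRUE, ddof = 0,
                                   subject_id = NA_integer_, roi_id = "roi") {
  parts <- lapply(runs, function(run) {
    if (zscore) run <- zscore_within_run(run, ddof = ddof)
    tent_delay_pattern(run, weights = weights, peak_shift = peak_shift,
                       epoch = epoch)
  })
  ids <- unlist(lapply(parts, attr, "trial_id"))
  mat <- do.call(rbind, parts)[order(ids), , drop = FALSE]
  delay_pattern(mat, subject_id = subject_id, roi_id = roi_id,
                peak_shift = as.integer(peak_shift))
}
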