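#' Paired-sample t-test with effect size
#'
#' Two-tailed paired t-test on subject-level measures, with Cohen's d for
#' paired designs: `d = mean(diff) / sd(diff)` using the sample SD.
#' Zero-variance differences are flagged as degenerate rather than
#' producing a spurious statistic.
#'
#' @param values_a,values_b Paired subject-level vectors.
#' @param mu Null value for the mean difference (default 0); `values_b`
#'   may be omitted to test `values_a` against `mu`.
#' @return An object of class `group_result`: `t`, `df`, `p`, `cohen_d`,
#'   `mean_diff`, `degenerate`.
#' @export
paired_test <- function(values_a, values_b = NULL, mu = 0) {
  d <- if (is.null(values_b)) values_a - mu else {
    if (length(values_a) != length(values_b)) {
      stop("paired vectors must have equal length")
    }
    values_a - values_b - mu
  }
  n <- length(d)
  if (n < 2L) stop("paired_test() needs n >= 2")
  sdd <- stats::sd(d)
  if (sdd == 0) {
    return(structure(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                          df = n - 1L, p = if (mean(d) == 0) 1 else 0,
                          cohen_d = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                          mean_diff = mean(d), degenerate = TRUE),
                     class = "group_result"))
  }
  tt <- stats::t.test(d)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, cohen_d = mean(d) / sdd,
                 mean_diff = mean(d), degenerate = FALSE),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g, Cohen's d = %.3f%s\n", x$df, x$t, x$p,
              x$cohen_d, if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Subject-level bootstrap p value
#'
#' Resamples subjects with replacement and computes an empirical
#' two-tailed p value for the statistic of the resampled values:
#' `p = 2 * min(frac <= 0, frac >= 0)`, floored at `1 / n_iter` (the
#' reporting resolution); p values below the floor are labelled
#' `"<0.001"` at the default 1000 iterations.
#'
#' @param values Subject-level values (e.g. paired differences).
#' @param statistic Function reducing a resample to a scalar (default
#'   [mean()]).
#' @param n_iter Number of bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @return A list: `p` (floored numeric), `label` (reporting string),
#'   `n_iter`, `seed`, `stats` (the resampled statistics).
#' @export
bootstrap_p <- function(values, statistic = mean, n_iter = 1000L, seed = 1L) {
  n <- length(values)
  if (n < 2L) stop("bootstrap_p() needs n >= 2")
  set.seed(as.integer(seed))
  stats_b <- vapply(seq_len(n_iter), function(i) {
    statistic(values[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  p_emp <- 2 * min(mean(stats_b <= 0), mean(stats_b >= 0))
  floor_p <- 1 / n_iter
  p <- max(min(p_emp, 1), floor_p)
  label <- if (p_emp < floor_p) paste0("<", format(floor_p)) else
    format(round(p, ceiling(log10(n_iter))))
  list(p = p, label = label, n_iter = as.integer(n_iter),
       seed = as.integer(seed), stats = stats_b)
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)` with an explicit family size `m`; the family
#' of comparisons is configuration, never inferred silently.
#'
#' @param p_values Uncorrected p values.
#' @param m Family size (default `length(p_values)`).
#' @param alpha Significance level for the rejection decisions.
#' @return A list with `p_adjusted` and logical `reject`.
#' @export
bonferroni <- function(p_values, m = length(p_values), alpha = 0.05) {
  stopifnot(m >= 1, all(p_values >= 0 & p_values <= 1))
  p_adj <- pmin(1, m * p_values)
  list(p_adjusted = p_adj, reject = p_adj < alpha, m = m, alpha = alpha)
}

#' Within-subject 2x2 interaction test
#'
#' Cue (cued vs. uncued) by region interaction for a complete
#' within-subject 2x2 design: the per-subject interaction contrast
#' `(cued - uncued)_regionA - (cued - uncued)_regionB` is tested against
#' 0; `F(1, n-1)` equals the squared paired t of that contrast, with the
#' identical two-tailed p.
#'
#' @param values Data frame with columns `subject`, `cue`, `region`,
#'   `value`; exactly one value per subject x cue x region cell.
#' @return A list: `F`, `df1`, `df2`, `p`, `contrast` (per subject).
#' @export
interaction_2x2 <- function(values) {
  req <- c("subject", "cue", "region", "value")
  if (!all(req %in% names(values))) {
    stop("values needs columns: ", paste(req, collapse = ", "))
  }
  cues <- as.character(sort(unique(values$cue)))
  regions <- as.character(sort(unique(values$region)))
  if (length(cues) != 2L || length(regions) != 2L) {
    stop("interaction_2x2() needs exactly two cue and two region levels")
  }
  tab <- stats::xtabs(value ~ subject + cue + region, data = values)
  if (any(stats::xtabs(~ subject + cue + region, data = values) != 1)) {
    stop("design must have exactly one value per subject x cue x region cell")
  }
  contrast <- (tab[, cues[1], regions[1]] - tab[, cues[2], regions[1]]) -
    (tab[, cues[1], regions[2]] - tab[, cues[2], regions[2]])
  res <- paired_test(contrast)
  list(F = res$t^2, df1 = 1L, df2 = res$df, p = res$p, contrast = contrast)
}

#' Balanced resampling contrast of small- vs. larger-error trials
#'
#' Equalizes trial counts between behavioral categories: on each of
#' `n_iter` iterations, draws (without replacement) as many small-error
#' trials as there are larger-error trials, averages the trialwise
#' measure, and averages across iterations. The larger-error estimate
#' uses all larger-error trials. Works on a per-trial scalar (R) or on
#' per-trial curves (a trials x grid matrix).
#'
#' @param measure Per-trial numeric vector, or matrix with one row per
#'   trial (aligned curves).
#' @param categories A [categorize_trials()] result (or a factor with
#'   levels small/larger/excluded) matching the trials.
#' @param n_iter Resampling iterations (default 5000).
#' @param seed Integer seed.
#' @param min_larger Minimum larger-error trials required (default 2);
#'   below it the subject is not estimable and an error is raised (catch
#'   and exclude the subject upstream).
#' @return A list: `small` (balanced estimate), `larger`, `difference`,
#'   `n_small`, `n_larger`, `n_iter`, `seed`.
#' @export
error_linked_contrast <- function(measure, categories, n_iter = 5000L,
                                  seed = 1L, min_larger = 2L) {
  labels <- if (inherits(categories, "trial_categorization")) {
    categories$labels
  } else categories
  mat <- if (is.matrix(measure)) measure else matrix(measure, ncol = 1L)
  stopifnot(nrow(mat) == length(labels))
  idx_small <- which(labels == "small")
  idx_larger <- which(labels == "larger")
  if (length(idx_larger) < min_larger) {
    stop("only ", length(idx_larger), " larger-error trials; subject not estimable")
  }
  if (length(idx_small) < length(idx_larger)) {
    stop("fewer small- than larger-error trials; balanced resampling undefined")
  }
  set.seed(as.integer(seed))
  nl <- length(idx_larger)
  acc <- matrix(0, 1L, ncol(mat))
  for (i in seq_len(n_iter)) {
    take <- idx_small[sample.int(length(idx_small), nl)]
    acc <- acc + colMeans(mat[take, , drop = FALSE])
  }
  small_est <- drop(acc / n_iter)
  larger_est <- drop(colMeans(mat[idx_larger, , drop = FALSE]))
  list(small = small_est, larger = larger_est,
       difference = small_est - larger_est,
       n_small = length(idx_small), n_larger = nl,
       n_iter = as.integer(n_iter), seed = as.integer(seed))
}

#' Correlate two subject-level measures
#'
#' Product-moment correlation across subjects with a two-tailed p value,
#' e.g. between IEM information and RSA association strength.
#'
#' @param per_subject_a,per_subject_b Paired subject-level scalars.
#' @return A list: `r`, `p`, `df`, `n`.
#' @export
correlate_measures <- function(per_subject_a, per_subject_b) {
  if (length(per_subject_a) != length(per_subject_b)) {
    stop("measures must be paired")
  }
  if (length(per_subject_a) < 3L) stop("correlate_measures() needs n >= 3")
  ct <- stats::cor.test(per_subject_a, per_subject_b)
  list(r = unname(ct$estimate), p = ct$p.value,
       df = unname(ct$parameter), n = length(per_subject_a))
}
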