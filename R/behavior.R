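#' Signed circular recall error
#'
#' The angular difference between the reported and the target (cued)
#' orientation on the 180-degree orientation circle, mapped to the
#' half-open interval `[-90, 90)`:
#' `((reported - target + 90) %% 180) - 90`.
#'
#' @param reported Reported orientation(s) in degrees.
#' @param target Target orientation(s) in degrees.
#' @return Signed errors in degrees, in `[-90, 90)`.
#' @examples
#' recall_error(10, 170)  # wraps to 20
#' @export
recall_error <- function(reported, target) {
  orientation_diff(reported, target)
}

#' Pooled empirical SD of recall errors
#'
#' The ordinary (linear) standard deviation of signed recall errors
#' pooled across subjects and trials, used to derive the 3-SD cut-off for
#' extra-large errors. The raw error distribution lives on `[-90, 90)`,
#' so a linear SD is well defined.
#'
#' @param errors Pooled signed recall errors in degrees.
#' @return The sample standard deviation in degrees.
#' @export
aggregate_error_sd <- function(errors) {
  errors <- as.numeric(errors)
  if (length(errors) < 2L || any(!is.finite(errors))) {
    stop("aggregate_error_sd() needs >= 2 finite errors")
  }
  stats::sd(errors)
}

#' Categorize trials by absolute recall error
#'
#' Splits trials into `small` (absolute error below `small_cut`),
#' `larger` (between `small_cut` and an upper bound, both inclusive at
#' the top, `small_cut <= e <= upper`), and `excluded` (beyond the upper
#' bound, attributed to lapses rather than imprecise memory). The upper
#' bound is either 3 times the pooled error SD (`upper_rule = "three_sd"`)
#' or a fixed cut-off, 45 degrees by default (`upper_rule = "fixed"`).
#'
#' @param errors Signed or absolute recall errors in degrees.
#' @param small_cut Small-error threshold in degrees, exclusive (default 20).
#' @param upper_rule `"three_sd"` or `"fixed"`.
#' @param sd_pooled Pooled error SD in degrees; required for
#'   `upper_rule = "three_sd"`.
#' @param upper_value Fixed upper cut-off in degrees (default 45), used
#'   when `upper_rule = "fixed"`.
#' @return An object of class `trial_categorization`: a list with
#'   `labels` (factor with levels small/larger/excluded), `small_cut`,
#'   `upper_rule` and the derived `upper_value`.
#' @export
categorize_trials <- function(errors, small_cut = 20,
                              upper_rule = c("three_sd", "fixed"),
                              sd_pooled = NULL, upper_value = 45) {
  upper_rule <- match.arg(upper_rule)
  abs_err <- abs(as.numeric(errors))
  if (any(!is.finite(abs_err))) stop("errors must be finite")
  upper <- if (upper_rule == "three_sd") {
    if (is.null(sd_pooled)) stop("upper_rule='three_sd' requires sd_pooled")
    3 * sd_pooled
  } else {
    upper_value
  }
  if (small_cut >= upper) {
    stop(sprintf("small_cut (%g) must be below the upper bound (%g)",
                 small_cut, upper))
  }
  labels <- factor(
    ifelse(abs_err < small_cut, "small",
           ifelse(abs_err <= upper, "larger", "excluded")),
    levels = c("small", "larger", "excluded"))
  structure(list(labels = labels, small_cut = small_cut,
                 upper_rule = upper_rule, upper_value = upper),
            class = "trial_categorization")
}

#' @export
print.trial_categorization <- function(x, ...) {
  tb <- table(x$labels)
  cat(sprintf(
    "trial_categorization: %d small, %d larger, %d excluded (<%g / <=%g deg)\n",
    tb[["small"]], tb[["larger"]], tb[["excluded"]], x$small_cut,
    x$upper_value))
  invisible(x)
}

#' Behavioral summary for one or more subjects
#'
#' @param trials Trial table(s) with `reported` and `theta_cued`.
#' @return A list with pooled signed errors, mean absolute error, pooled
#'   SD, and the fraction of trials with absolute error below 45 degrees.
#' @export
behavior_summary <- function(trials) {
  err <- recall_error(trials$reported, trials$theta_cued)
  list(signed_errors = err,
       mean_abs_error = mean(abs(err)),
       error_sd = aggregate_error_sd(err),
       frac_within_45 = mean(abs(err) < 45))
}
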