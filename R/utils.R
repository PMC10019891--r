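#' Signed circular difference between orientations
#'
#' Orientations live on a 180-degree circle. The signed difference
#' `a - b` is mapped to the half-open interval `[-90, 90)`.
#'
#' @param a,b Orientations in degrees.
#' @return Signed differences in degrees, in `[-90, 90)`.
#' @export
orientation_diff <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("orientation_diff(): inputs must be finite")
  }
  ((a - b + 90) %% 180) - 90
}

#' Circular orientation distance
#'
#' Absolute distance on the 180-degree orientation circle, in `[0, 90]`.
#'
#' @param a,b Orientations in degrees.
#' @return Distances in degrees.
#' @export
orientation_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Wrap orientations to `[0, 180)`
#' @param theta Orientations in degrees.
#' @return Wrapped orientations.
#' @export
wrap_orientation <- function(theta) theta %% 180

# internal: stopifnot-style scalar checks with readable messages
.check_scalar <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop(sprintf("'%s' must be a finite scalar in [%s, %s]", name, min, max))
  }
  invisible(x)
}

# internal: derive a reproducible stream seed below 2^31 from a base seed
.substream_seed <- function(seed, offset) {
  (as.integer(seed) + 104729L * as.integer(offset)) %% 2147483647L
}
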