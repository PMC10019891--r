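#' Idealized orientation information channels
#'
#' Constructs the basis of idealized, nonnegative orientation channels used
#' by the forward encoding model. Each channel is a half-wave rectified
#' sinusoid over the 180-degree orientation space raised to a power,
#' \deqn{f_k(\theta) = \max(0, \cos(\pi d_k / 180))^p,}
#' where \eqn{d_k} is the signed circular difference between \eqn{\theta}
#' and the channel's center mapped to \eqn{[-90, 90)}. A channel responds
#' maximally (1) at its own center and is exactly 0 at the orthogonal
#' orientation 90 degrees away.
#'
#' @param n_channels Number of channels (default 9).
#' @param centers Channel centers in degrees; default evenly spaced
#'   `0, 20, ..., 160`, matching the nine base stimulus orientations.
#' @param exponent Power applied to the rectified sinusoid (default 8).
#' @param space Periodicity of the feature space in degrees (180 for
#'   orientation).
#' @return An object of class `channel_basis`.
#' @examples
#' b <- channel_basis()
#' channel_response(b, 40)  # peaks at the 40-degree channel
#' @export
channel_basis <- function(n_channels = 9L,
                          centers = seq(0, 160, by = 20),
                          exponent = 8,
                          space = 180) {
  .check_scalar(n_channels, "n_channels", min = 1)
  .check_scalar(exponent, "exponent", min = .Machine$double.eps)
  .check_scalar(space, "space", min = 1)
  centers <- as.numeric(centers)
  if (length(centers) != n_channels) {
    stop("length(centers) must equal n_channels")
  }
  if (anyDuplicated(centers %% space)) {
    stop("channel centers must be distinct modulo the feature space")
  }
  structure(
    list(n_channels = as.integer(n_channels), centers = centers,
         exponent = exponent, space = space),
    class = "channel_basis"
  )
}

#' @export
print.channel_basis <- function(x, ...) {
  cat(sprintf("channel_basis: %d channels over %g deg, exponent %g\n",
              x$n_channels, x$space, x$exponent))
  cat("centers:", paste(x$centers, collapse = ", "), "\n")
  invisible(x)
}

#' Channel responses for one or more orientations
#'
#' @param basis A [channel_basis()].
#' @param theta Orientation(s) in degrees.
#' @return A numeric matrix, `length(theta)` rows by `n_channels` columns;
#'   for a single orientation a plain vector of `n_channels` responses.
#' @export
channel_response <- function(basis, theta) {
  stopifnot(inherits(basis, "channel_basis"))
  if (!is.numeric(theta) || any(!is.finite(theta))) {
    stop("theta must be finite numeric")
  }
  resp <- .channel_resp_matrix(basis, theta)
  if (length(theta) == 1L) drop(resp) else resp
}

# internal: always a length(theta) x k matrix
.channel_resp_matrix <- function(basis, theta) {
  half <- basis$space / 2
  d <- ((outer(theta, basis$centers, "-") + half) %% basis$space) - half
  pmax(cos(pi * d / basis$space), 0)^basis$exponent
}

#' Channel design matrix
#'
#' Evaluates the channel basis at each trial's orientation label, giving
#' the matrix `C` (channels x trials) of the forward model `B = W C + N`.
#'
#' @param basis A [channel_basis()].
#' @param thetas Orientation labels in degrees, one per trial.
#' @return Numeric matrix, `n_channels` x `length(thetas)`.
#' @export
design_matrix <- function(basis, thetas) {
  if (length(thetas) == 0L) stop("design_matrix(): no trials supplied")
  stopifnot(inherits(basis, "channel_basis"))
  t(.channel_resp_matrix(basis, as.numeric(thetas)))
}
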