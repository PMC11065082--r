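#' Discretized circular neural space
#'
#' A ring attractor's neurons are parameterized by an angle on the unit
#' circle. `ring_grid()` discretizes the circle into `n` uniformly spaced
#' bins with angles at `psi_j = 2*pi*j/n`, `j = 0, ..., n-1`.
#'
#' @param n Number of neurons (positive integer, at least 16).
#' @return An object of class `ring_grid` with fields `n`, `angles`
#'   (radians, in `[0, 2*pi)`) and `dpsi` (the bin width `2*pi/n`, used as
#'   quadrature weight throughout the package).
#' @examples
#' g <- ring_grid(64)
#' range(g$angles)
#' @export
ring_grid <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 16L)
    stop("ring_grid: 'n' must be an integer >= 16")
  structure(
    list(n = n, angles = 2 * pi * (seq_len(n) - 1L) / n, dpsi = 2 * pi / n),
    class = "ring_grid"
  )
}

#' @export
print.ring_grid <- function(x, ...) {
  cat(sprintf("<ring_grid> n = %d neurons, bin width = %.5f rad\n",
              x$n, x$dpsi))
  invisible(x)
}

#' Wrap angles to (-pi, pi]
#'
#' Circular differences (positional errors, angular offsets) are wrapped to
#' the principal interval `(-pi, pi]`.
#'
#' @param x Numeric vector of angles in radians.
#' @return Wrapped angles in `(-pi, pi]`.
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # %% maps -pi to -pi; the convention here is (-pi, pi]
  y[y == -pi] <- pi
  y
}

#' Wrap angles to [0, 2*pi)
#'
#' @param x Numeric vector of angles in radians.
#' @return Wrapped angles in `[0, 2*pi)`.
#' @export
wrap_2pi <- function(x) x %% (2 * pi)

#' Circularly shift a vector by whole bins
#'
#' `circ_shift(x, m)` moves entry `j` to position `j + m` (mod n), i.e. a
#' positive `m` rotates the pattern counter-clockwise on the ring grid.
#'
#' @param x Numeric vector.
#' @param m Integer number of bins (may be negative).
#' @return Shifted vector of the same length.
#' @export
circ_shift <- function(x, m) {
  n <- length(x)
  m <- ((as.integer(m)) %% n + n) %% n
  if (m == 0L) return(x)
  c(x[(n - m + 1L):n], x[1L:(n - m)])
}

#' Unwrap a sampled circular trajectory
#'
#' Removes 2*pi jumps from a time series of wrapped angles so that total
#' accumulated rotation can be measured (e.g. for gain estimation from bump
#' drift over several laps).
#'
#' @param theta Numeric vector of angles (radians), sampled densely enough
#'   that successive differences are below pi in magnitude.
#' @return Unwrapped angles; the first element is unchanged.
#' @export
unwrap_angles <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- wrap_angle(diff(theta))
  theta[1L] + c(0, cumsum(d))
}

# Central differences of a periodic function sampled on the ring grid.
circ_gradient <- function(x, dpsi) {
  n <- length(x)
  (circ_shift(x, -1L) - circ_shift(x, 1L)) / (2 * dpsi)
}

# Second central difference of a periodic sample.
circ_laplacian <- function(x, dpsi) {
  (circ_shift(x, -1L) - 2 * x + circ_shift(x, 1L)) / dpsi^2
}
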