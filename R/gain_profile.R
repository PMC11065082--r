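#' Analytic spatially distributed path-integration gain
#'
#' Evaluates the reduced-model expression for the network's
#' path-integration (PI) gain as a function of the bump location `theta`:
#'
#' \deqn{k(\theta) = \frac{-b}{\tau_c \|\partial_\psi r_c^*\|^2}
#'   \int_0^{2\pi} \partial^2_\psi r_c^*(\psi-\theta)
#'   \sum_{i \in \{cw, ccw\}} \alpha_i W_{i\text{-}c}(\psi) W_{v\text{-}i}(\psi)
#'   \, \mathrm{sign}\, r_i^*(\psi,\theta,0) \, d\psi}
#'
#' where `b` is the rotation-to-central connection offset (radians),
#' `r_c^*` the rest-state central bump, `r_i^*` the rest-state rotation
#' bumps, and the weights are evaluated at the presynaptic neuron. The
#' squared norm in the denominator is the L2 norm of the bump gradient over
#' the ring; `sign(r_i^*)` is the indicator of nonzero rotation-ring
#' activity at rest (rates are rectified, so sign is 0 or 1). Derivatives
#' are central differences on the ring grid and the integrals are bin-width
#' weighted sums.
#'
#' When the velocity-to-rotation weights are spatially uniform the gain is
#' constant in `theta`; nonuniform weights make the gain inhomogeneous --
#' the network over- or under-represents parts of the track.
#'
#' @param params A `network_params` (its stored rest-state templates are
#'   used unless overridden).
#' @param rc_template,rcw_template,rccw_template Optional converged bump
#'   templates (peak at angle 0) overriding those in `params`.
#' @return An object of class `gain_profile`: list with `theta` (the grid
#'   angles), `k_values`, `k0` (spatial average) and `kac_values`
#'   (deviation `k - k0`, zero mean).
#' @export
compute_pi_gain_profile <- function(params, rc_template = params$rc_template,
                                    rcw_template = params$rcw_template,
                                    rccw_template = params$rccw_template) {
  g <- params$grid
  n <- g$n
  rc1 <- circ_gradient(rc_template, g$dpsi)
  rc2 <- circ_laplacian(rc_template, g$dpsi)
  grad_norm2 <- sum(rc1^2) * g$dpsi
  if (grad_norm2 < 1e-12 * max(1, max(rc_template))^2)
    stop("compute_pi_gain_profile: degenerate (flat) bump template")
  ind_cw <- as.numeric(rcw_template > 0)
  ind_ccw <- as.numeric(rccw_template > 0)
  w_cw <- params$alpha_cw * params$w_cw_c * params$Wv_cw
  w_ccw <- params$alpha_ccw * params$w_ccw_c * params$Wv_ccw
  k_values <- numeric(n)
  for (j in seq_len(n)) {
    sh <- j - 1L
    integrand <- circ_shift(rc2, sh) *
      (w_cw * circ_shift(ind_cw, sh) + w_ccw * circ_shift(ind_ccw, sh))
    k_values[j] <- -params$b / (params$tau_c * grad_norm2) *
      sum(integrand) * g$dpsi
  }
  k0 <- mean(k_values)
  structure(list(theta = g$angles, k_values = k_values, k0 = k0,
                 kac_values = k_values - k0),
            class = "gain_profile")
}

#' @export
print.gain_profile <- function(x, ...) {
  cat(sprintf("<gain_profile> k0 = %.4f, range %.4f .. %.4f over %d angles\n",
              x$k0, min(x$k_values), max(x$k_values), length(x$theta)))
  invisible(x)
}

#' Spatial average of a gain profile
#'
#' The circle average `(1 / 2 pi) * integral k(theta) d theta`; for
#' uniformly spaced samples the trapezoid rule on the circle reduces to the
#' arithmetic mean.
#'
#' @param profile A `gain_profile` (or a bare numeric vector of gain
#'   samples on a uniform grid).
#' @return The dimensionless average gain `k0`.
#' @export
spatial_average <- function(profile) {
  if (inherits(profile, "gain_profile")) mean(profile$k_values)
  else mean(as.numeric(profile))
}

#' Measure the path-integration gain profile from a full-network run
#'
#' Empirical counterpart of [compute_pi_gain_profile()]: drives the full
#' network at constant velocity for one lap (landmarks off), decodes the
#' bump trajectory, and estimates the local bump speed by least-squares
#' slope fits over sliding time windows. The local gain is the fitted
#' speed divided by `v`, reported at the window-centre bump location.
#'
#' With `bidirectional = TRUE` (default) the probe is run once in each
#' direction and the two estimates are averaged on a common grid of bump
#' locations. The moving bump trails its quasi-static speed slightly (the
#' network's non-translation modes relax over a finite time), which shifts
#' a one-directional profile estimate along the direction of travel; the
#' lag is odd in the probe velocity, so the bidirectional average cancels
#' it to first order.
#'
#' @param params A `network_params`.
#' @param v Probe velocity magnitude (rad/s), nonzero.
#' @param window Slope-fit window length (seconds).
#' @param record_dt Trajectory sampling interval (seconds).
#' @param transient Settling time discarded at the start (seconds).
#' @param bidirectional Probe both travel directions and average.
#' @param n_bins Number of bump-location bins for the bidirectional
#'   average.
#' @return A data frame with columns `theta` (bump location, radians) and
#'   `k_measured` (dimensionless local gain).
#' @export
measure_gain_profile <- function(params, v = 0.6, window = 0.25,
                                 record_dt = 0.02, transient = 1,
                                 bidirectional = TRUE, n_bins = 32L) {
  if (v == 0) stop("measure_gain_profile: 'v' must be nonzero")
  if (bidirectional) {
    m_fwd <- measure_gain_profile(params, abs(v), window, record_dt,
                                  transient, bidirectional = FALSE)
    m_bwd <- measure_gain_profile(params, -abs(v), window, record_dt,
                                  transient, bidirectional = FALSE)
    breaks <- seq(0, 2 * pi, length.out = n_bins + 1L)
    binned <- function(m) {
      b <- findInterval(m$theta, breaks, rightmost.closed = TRUE)
      out <- rep(NA_real_, n_bins)
      agg <- tapply(m$k_measured, b, mean)
      out[as.integer(names(agg))] <- agg
      out
    }
    k_sym <- (binned(m_fwd) + binned(m_bwd)) / 2
    ctr <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
    ok <- is.finite(k_sym)
    return(data.frame(theta = ctr[ok], k_measured = k_sym[ok]))
  }
  # cover a full lap even where the local gain runs well below 1
  dur <- transient + 2 * pi / (0.55 * abs(v)) + window
  tr <- simulate_network(params, velocity = v, duration = dur,
                         record_dt = record_dt)
  keep <- tr$t >= transient
  th <- unwrap_angles(tr$theta[keep])
  tt <- tr$t[keep]
  half <- max(2L, round(window / 2 / record_dt))
  idx <- seq.int(half + 1L, length(th) - half)
  k_meas <- vapply(idx, function(i) {
    sel <- (i - half):(i + half)
    stats::cov(tt[sel], th[sel]) / stats::var(tt[sel]) / v
  }, numeric(1))
  data.frame(theta = wrap_2pi(th[idx]), k_measured = k_meas)
}

#' Evaluate the gain deviation profile at an angle
#'
#' Linear interpolation of `kac(theta) = k(theta) - k0` on the circle.
#'
#' @param profile A `gain_profile` or `NULL` (returns 0).
#' @param theta Angle(s) in radians.
#' @return `kac` evaluated at `theta`.
#' @export
kac_at <- function(profile, theta) {
  if (is.null(profile)) return(rep(0, length(theta)))
  th <- wrap_2pi(theta)
  n <- length(profile$theta)
  dpsi <- 2 * pi / n
  j <- floor(th / dpsi)
  frac <- th / dpsi - j
  j0 <- (j %% n) + 1L
  j1 <- ((j + 1L) %% n) + 1L
  (1 - frac) * profile$kac_values[j0] + frac * profile$kac_values[j1]
}
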