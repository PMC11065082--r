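#' Synthetic animal velocity profiles
#'
#' Generates the velocity traces v(t) used throughout the simulations. The
#' track is taken as a circular track of unit circumference, so position
#' maps 1:1 onto the ring angle and velocity is expressed in radians per
#' second; a typical running speed of one track lap per ~6 s corresponds to
#' `mean_v = 1`.
#'
#' Kinds:
#' \describe{
#'   \item{`constant`}{`v == mean_v` throughout.}
#'   \item{`pause_resume`}{`mean_v` with zero-velocity pauses; the defaults
#'     place 30 s pauses starting at minutes 5 and 20 of a 30-minute run,
#'     mirroring the pause-and-run structure of a rat's track session.}
#'   \item{`smoothed_random`}{positive, low-pass filtered
#'     Ornstein--Uhlenbeck-style speed fluctuations around `mean_v` with
#'     occasional pauses; a behavioural fixture, not a behavioural model.}
#' }
#'
#' @param kind One of `"constant"`, `"pause_resume"`, `"smoothed_random"`.
#' @param duration Total duration in seconds (> 0).
#' @param mean_v Mean running speed (rad/s).
#' @param dt Sampling interval of the profile in seconds.
#' @param pauses For `pause_resume`: a 2-column matrix (or list of length-2
#'   vectors) of pause start/end times in seconds. Defaults to
#'   `[300, 330]` and `[1200, 1230]`.
#' @param seed Integer seed (used by `smoothed_random` only); recorded in
#'   the returned object for reproducibility.
#' @param tau_ou Correlation time (s) of the smoothed-random fluctuations.
#' @param sd_v Standard deviation of the smoothed-random fluctuations.
#' @param pause_prob Per-minute probability of a 10 s pause inserted in a
#'   smoothed-random profile.
#' @return An object of class `velocity_profile`: list with `times`, `v`,
#'   `kind`, `dt`, `seed`.
#' @examples
#' vp <- make_velocity_profile("pause_resume", duration = 1800, mean_v = 1)
#' all(vp$v[vp$times >= 300 & vp$times < 330] == 0)
#' @export
make_velocity_profile <- function(kind = c("constant", "pause_resume",
                                           "smoothed_random"),
                                  duration, mean_v = 1, dt = 0.01,
                                  pauses = NULL, seed = 1L,
                                  tau_ou = 10, sd_v = 0.3,
                                  pause_prob = 0.15) {
  kind <- match.arg(kind)
  if (duration <= 0) stop("make_velocity_profile: 'duration' must be > 0")
  times <- seq(0, duration, by = dt)
  v <- rep(mean_v, length(times))
  if (kind == "pause_resume") {
    if (is.null(pauses)) pauses <- rbind(c(300, 330), c(1200, 1230))
    if (is.list(pauses)) pauses <- do.call(rbind, pauses)
    for (i in seq_len(nrow(pauses))) {
      v[times >= pauses[i, 1] & times < pauses[i, 2]] <- 0
    }
  } else if (kind == "smoothed_random") {
    set.seed(seed)
    n <- length(times)
    x <- numeric(n)
    a <- exp(-dt / tau_ou)
    s <- sd_v * sqrt(1 - a^2)
    innov <- stats::rnorm(n, 0, s)
    for (i in 2:n) x[i] <- a * x[i - 1] + innov[i]
    v <- pmax(mean_v + x, 0)
    # occasional complete stops
    minute_starts <- if (duration >= 60) seq(0, duration - 60, by = 60)
                     else numeric(0)
    stops <- minute_starts[stats::runif(length(minute_starts)) < pause_prob]
    for (t0 in stops) {
      off <- stats::runif(1, 0, 50)
      v[times >= t0 + off & times < t0 + off + 10] <- 0
    }
  }
  structure(list(times = times, v = v, kind = kind, dt = dt, seed = seed,
                 mean_v = mean_v),
            class = "velocity_profile")
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("<velocity_profile> kind = %s, %.0f s @ dt = %g s, mean v = %.3f rad/s\n",
              x$kind, max(x$times), x$dt, mean(x$v)))
  invisible(x)
}

# Piecewise-constant lookup of v at arbitrary times (profiles are sampled
# on a uniform grid; simulation steps may be finer).
velocity_at <- function(profile, t) {
  i <- pmin(pmax(floor(t / profile$dt) + 1L, 1L), length(profile$v))
  profile$v[i]
}

#' Velocity-neuron tuning curves
#'
#' The clockwise (CW) velocity neuron decreases its rate with the animal's
#' (counter-clockwise positive) velocity, `u_cw0 - alpha_cw * v`, while the
#' counter-clockwise (CCW) velocity neuron increases it,
#' `u_ccw0 + alpha_ccw * v`; both are rectified at zero. The push-pull
#' difference of the pair is what drives the rotation rings differentially.
#'
#' @param v Velocity (rad/s), scalar or vector.
#' @param params A `network_params` object (fields `u_cw0`, `u_ccw0`,
#'   `alpha_cw`, `alpha_ccw`, `rectify_mode`).
#' @return A list with components `cw` and `ccw` (rates, Hz).
#' @export
velocity_neuron_rates <- function(v, params) {
  cw <- params$u_cw0 - params$alpha_cw * v
  ccw <- params$u_ccw0 + params$alpha_ccw * v
  if (any(cw < 0) || any(ccw < 0)) {
    msg <- sprintf(
      "velocity %.3g rad/s rectifies a velocity neuron to zero (linear range |v| <= %.3g)",
      max(abs(v)), min(params$u_cw0 / params$alpha_cw,
                       params$u_ccw0 / params$alpha_ccw))
    if (identical(params$rectify_mode, "error")) stop(msg) else warning(msg)
  }
  list(cw = pmax(cw, 0), ccw = pmax(ccw, 0))
}

#' Visual-landmark protocol
#'
#' Describes the experimentally controlled visual gain `k_star` (the ratio
#' between landmark movement and animal movement; `k_star = 1` is the
#' veridical condition with stationary landmarks) and the schedule of
#' landmark-off intervals (landmark extinction probes). While landmarks are
#' on, the visual drive's peak advances as `d theta_star / dt = k_star * v`;
#' while off, the visual current is zero and `theta_star` continues to be
#' integrated silently.
#'
#' @param k_star Constant visual gain, or a 2-column matrix
#'   `(time, k_star)` giving a piecewise-constant schedule (value holds from
#'   its time onward).
#' @param landmark_off_intervals Optional list of `c(start, end)` intervals
#'   (seconds) during which landmarks are extinguished; must not overlap.
#' @return An object of class `visual_protocol`.
#' @export
make_visual_protocol <- function(k_star = 1, landmark_off_intervals = list()) {
  if (is.matrix(k_star)) {
    if (ncol(k_star) != 2 || is.unsorted(k_star[, 1]))
      stop("make_visual_protocol: schedule must be a sorted (time, k_star) matrix")
  }
  if (length(landmark_off_intervals)) {
    iv <- do.call(rbind, landmark_off_intervals)
    if (any(iv[, 2] <= iv[, 1]))
      stop("make_visual_protocol: empty or inverted off-interval")
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2]))
      stop("make_visual_protocol: overlapping off-intervals")
    landmark_off_intervals <- lapply(seq_len(nrow(iv)), function(i) iv[i, ])
  }
  structure(list(k_star = k_star,
                 landmark_off_intervals = landmark_off_intervals),
            class = "visual_protocol")
}

# Evaluate the protocol at time t.
k_star_at <- function(protocol, t) {
  ks <- protocol$k_star
  if (!is.matrix(ks)) return(rep(ks, length(t)))
  idx <- findInterval(t, ks[, 1])
  ks[pmax(idx, 1L), 2]
}

landmarks_on_at <- function(protocol, t) {
  on <- rep(TRUE, length(t))
  for (iv in protocol$landmark_off_intervals) {
    on[t >= iv[1] & t < iv[2]] <- FALSE
  }
  on
}
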