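#' Sinusoidal landmark-correction feedback
#'
#' The reduced model's landmark term `beta` maps the wrapped positional
#' error to a corrective rotation rate. Any function that takes the sign
#' of its argument near zero yields stable correction; the sinusoid
#' `beta(x) = amplitude * sin(x)` is the canonical smooth choice on the
#' circle (zero at 0 and at the antipode, maximal restoring rate at
#' `pi/2`).
#'
#' @param amplitude Peak correction rate (1/s), > 0.
#' @return An object of class `feedback_function`: list with `fun` (the
#'   map), `amplitude` and `label`.
#' @examples
#' b <- beta_sinusoidal(0.66)
#' b$fun(pi / 2)    # 0.66
#' @export
beta_sinusoidal <- function(amplitude) {
  if (amplitude <= 0) stop("beta_sinusoidal: 'amplitude' must be > 0")
  force(amplitude)
  structure(list(fun = function(x) amplitude * sin(x),
                 amplitude = amplitude,
                 label = sprintf("%.3g*sin", amplitude)),
            class = "feedback_function")
}

#' Reduced-model state
#'
#' @param theta Bump location (radians).
#' @param theta_star Visual-drive (landmark) location (radians).
#' @param k0 Current spatial-average path-integration gain.
#' @param t Time (seconds).
#' @return An object of class `reduced_state`.
#' @export
reduced_state <- function(theta = 0, theta_star = 0, k0 = 1, t = 0) {
  structure(list(theta = wrap_2pi(theta), theta_star = wrap_2pi(theta_star),
                 k0 = k0, t = t),
            class = "reduced_state")
}

#' Simulate the reduced bump-location model
#'
#' Integrates the one-dimensional model of the attractor's position
#' representation under velocity input, landmark feedback and an optional
#' adaptive gain rule:
#' \deqn{d\theta^*/dt = k^* v, \quad
#'       d\theta/dt = \beta(\theta^* - \theta) + (k_0 + k_{ac}(\theta)) v,
#'       \quad dk_0/dt = g_0(k_0, \tilde\theta, v)}
#' with the landmark term dropped while landmarks are off. Angles are
#' integrated on the real line and wrapped on output; the positional error
#' is always wrapped to `(-pi, pi]`.
#'
#' @param initial A [reduced_state()].
#' @param velocity A [velocity_profile], a function of time, or a constant
#'   (rad/s).
#' @param k_star Visual gain (constant), or a [visual_protocol] carrying a
#'   gain schedule and landmark-off intervals.
#' @param beta A [feedback_function].
#' @param rule Optional [gain_rule]; when supplied, `k0` evolves.
#' @param kac Optional [gain_profile] whose deviation `kac(theta)` makes
#'   the gain spatially inhomogeneous; `NULL` for a homogeneous gain.
#' @param duration Simulated time (seconds).
#' @param dt Integrator step (seconds).
#' @param landmarks_off_after Time (seconds) after which the landmark term
#'   is dropped (`Inf` = never); ignored when `k_star` is a protocol with
#'   its own off-intervals.
#' @param method `"rk4"` (default) or `"euler"` (parity with the full
#'   network's integrator).
#' @param record_dt Sampling interval of the returned trajectory.
#' @return A `trajectory` data frame with columns `t`, `v`, `theta`,
#'   `theta_star`, `theta_tilde`, `k0`, `k_star`, `landmarks_on`. The
#'   final `reduced_state` is attached as attribute `"final_state"`.
#' @export
simulate_reduced <- function(initial, velocity, k_star, beta, rule = NULL,
                             kac = NULL, duration, dt = 0.01,
                             landmarks_off_after = Inf,
                             method = c("rk4", "euler"), record_dt = 0.1) {
  method <- match.arg(method)
  stopifnot(inherits(initial, "reduced_state"),
            inherits(beta, "feedback_function"))
  if (dt <= 0 || dt > 0.5 / beta$amplitude)
    stop("simulate_reduced: 'dt' must be positive and small relative to the feedback rate")
  vfun <- as_velocity_function(velocity)
  if (inherits(k_star, "visual_protocol")) {
    proto <- k_star
  } else {
    off <- if (is.finite(landmarks_off_after))
      list(c(landmarks_off_after, Inf)) else list()
    proto <- make_visual_protocol(k_star = k_star,
                                  landmark_off_intervals = off)
  }
  bfun <- beta$fun
  gfun <- if (is.null(rule)) NULL else rule$g0
  kacf <- function(th) kac_at(kac, th)

  theta <- initial$theta
  theta_star <- initial$theta_star
  k0 <- initial$k0
  steps <- ceiling(duration / dt)
  rec_every <- max(1L, round(record_dt / dt))
  n_rec <- floor(steps / rec_every) + 1L
  out <- data.frame(t = numeric(n_rec), v = numeric(n_rec),
                    theta = numeric(n_rec), theta_star = numeric(n_rec),
                    theta_tilde = numeric(n_rec), k0 = numeric(n_rec),
                    k_star = numeric(n_rec), landmarks_on = logical(n_rec))
  rec <- function(i, t, v, ks, on) {
    out$t[i] <<- t; out$v[i] <<- v
    out$theta[i] <<- wrap_2pi(theta)
    out$theta_star[i] <<- wrap_2pi(theta_star)
    out$theta_tilde[i] <<- wrap_angle(theta_star - theta)
    out$k0[i] <<- k0
    out$k_star[i] <<- ks
    out$landmarks_on[i] <<- on
  }
  rec(1L, 0, vfun(0), k_star_at(proto, 0), landmarks_on_at(proto, 0))
  ri <- 1L
  for (s in seq_len(steps)) {
    t0 <- (s - 1L) * dt
    v <- vfun(t0)        # velocity held constant across the step
    ks <- k_star_at(proto, t0)
    on <- landmarks_on_at(proto, t0)
    derivs <- function(th, ths, k) {
      dth <- (k + kacf(th)) * v
      if (on) dth <- dth + bfun(wrap_angle(ths - th))
      dk <- if (is.null(gfun)) 0 else gfun(k, wrap_angle(ths - th), v)
      c(dth, ks * v, dk)
    }
    if (method == "euler") {
      d <- derivs(theta, theta_star, k0)
      theta <- theta + dt * d[1L]
      theta_star <- theta_star + dt * d[2L]
      k0 <- k0 + dt * d[3L]
    } else {
      k1 <- derivs(theta, theta_star, k0)
      k2 <- derivs(theta + dt / 2 * k1[1L], theta_star + dt / 2 * k1[2L],
                   k0 + dt / 2 * k1[3L])
      k3 <- derivs(theta + dt / 2 * k2[1L], theta_star + dt / 2 * k2[2L],
                   k0 + dt / 2 * k2[3L])
      k4 <- derivs(theta + dt * k3[1L], theta_star + dt * k3[2L],
                   k0 + dt * k3[3L])
      incr <- (k1 + 2 * k2 + 2 * k3 + k4) / 6
      theta <- theta + dt * incr[1L]
      theta_star <- theta_star + dt * incr[2L]
      k0 <- k0 + dt * incr[3L]
    }
    if (s %% rec_every == 0L) {
      ri <- ri + 1L
      rec(ri, s * dt, v, ks, on)
    }
  }
  out <- out[seq_len(ri), ]
  class(out) <- c("trajectory", "data.frame")
  attr(out, "final_state") <- reduced_state(theta, theta_star, k0,
                                            t = steps * dt)
  attr(out, "dt") <- dt
  out
}
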