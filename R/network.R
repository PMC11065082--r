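#' Parameters of the unconstrained ring attractor network
#'
#' Assembles the three-ring firing-rate model: a central ring with
#' local-excitation/global-inhibition recurrence, clockwise (CW) and
#' counter-clockwise (CCW) rotation rings that conjoin position and
#' velocity, velocity neurons with push-pull tuning, and a bump-shaped
#' visual drive. Rotation-ring neurons are treated as fast relative to the
#' central ring and follow their inputs instantaneously (the standard
#' quasi-steady-state treatment behind the rotation-ring rate ansatz).
#'
#' Wiring conventions. Central-to-rotation connections are topographic with
#' per-neuron weight `g_c_rot`. Velocity-to-rotation connections have
#' per-neuron weights `Wv_cw(psi)`, `Wv_ccw(psi)` (possibly nonuniform --
#' this spatial freedom is what makes the path-integration gain a
#' distributed quantity). Rotation-to-central connections are one-to-one
#' with an angular offset of `b_bins` whole bins: the CCW ring projects
#' `b_bins` bins ahead (counter-clockwise) and the CW ring the same number
#' of bins behind, forming the push-pull pair that shifts the bump.
#' Global inhibition onto each rotation ring is set to cancel its baseline
#' velocity drive plus a positive margin `i_margin`, so that at rest the
#' rotation rings fire only under the central bump's footprint and the bump
#' stays put for any weight profile (the balanced-input condition for
#' immobility invariance).
#'
#' Amplitude stabilization. A rectified-linear attractor is positively
#' homogeneous, so excitatory loops alone leave the bump amplitude
#' unstable. The full model therefore adds an activity-dependent global
#' inhibition onto the central ring, `-gamma_inh * (mean(r_cw) +
#' mean(r_ccw))`, together with a small uniform tonic drive `I_tonic`.
#' Because this inhibition is spatially uniform it exerts no push on the
#' bump (and does not enter the path-integration gain); it grows
#' superlinearly with bump amplitude and therefore pins it. The bump's
#' location remains free (a continuous attractor) because the wiring is
#' rotation invariant.
#'
#' If `calibrate = TRUE`, the velocity-to-rotation weight scale is adjusted
#' so that the spatial average of the analytic path-integration gain equals
#' `target_gain` (the shape of `Wv_mod` is preserved; only its scale moves).
#'
#' @param n Number of neurons per ring.
#' @param tau_c Synaptic time constant of central-ring neurons (seconds).
#' @param excit_width,excit_amp,inhib_amp Recurrent-kernel shape, see
#'   [build_recurrent_kernel()].
#' @param g_c_rot Central-to-rotation topographic weight (scalar).
#' @param w_rot_c Rotation-to-central weight; scalar or length-`n` vector
#'   (applies to both rings unless `w_cw_c`/`w_ccw_c` given).
#' @param w_cw_c,w_ccw_c Optional per-ring rotation-to-central weight
#'   vectors (presynaptic indexing).
#' @param b_bins Whole-bin angular offset of the rotation-to-central
#'   connections (the offset `b` is `b_bins * 2 * pi / n` radians).
#' @param u_cw0,u_ccw0 Velocity-neuron baseline rates (Hz).
#' @param alpha_cw,alpha_ccw Absolute velocity-tuning slopes (Hz per rad/s).
#' @param Wv_mod Spatial modulation profile of the velocity-to-rotation
#'   weights: scalar 1 for uniform, or a length-`n` positive vector
#'   (applied to both rings, preserving CW/CCW symmetry).
#' @param i_margin Activation margin (Hz) by which global inhibition
#'   exceeds the baseline velocity drive on the rotation rings; gates the
#'   rotation rings to the central bump's footprint.
#' @param cc_gain Scaling of the recurrent kernel in the full model
#'   (1 keeps the kernel at its normalized critical gain).
#' @param I_tonic Uniform tonic drive (Hz) to the central ring in the full
#'   model.
#' @param gamma_inh Gain of the activity-dependent global inhibition fed
#'   back from the rotation rings onto the central ring; stabilizes the
#'   bump amplitude.
#' @param vis_amp Peak amplitude of the visual drive current, as a fraction
#'   of the converged central bump's peak rate.
#' @param target_gain Desired spatial-average path-integration gain.
#' @param calibrate Logical; scale velocity weights to hit `target_gain`.
#' @param rectify_mode `"warn"` (default) or `"error"`: behaviour when a
#'   velocity exceeds the velocity neurons' linear range.
#' @return An object of class `network_params`. Notable computed fields:
#'   `rc_template`, `rcw_template`, `rccw_template` (converged rest-state
#'   bumps, peak at angle 0), `rho_vis` (visual current profile), and
#'   `gain_profile` (the analytic [gain_profile] at rest).
#' @export
network_params <- function(n = 256, tau_c = 0.01,
                           excit_width = 0.55, excit_amp = 1,
                           inhib_amp = 0.12,
                           g_c_rot = 0.5, w_rot_c = 0.4,
                           w_cw_c = NULL, w_ccw_c = NULL,
                           b_bins = 5L,
                           u_cw0 = 30, u_ccw0 = 30,
                           alpha_cw = 10, alpha_ccw = 10,
                           Wv_mod = 1,
                           i_margin = 15,
                           cc_gain = 1, I_tonic = 2, gamma_inh = 2.5,
                           vis_amp = 0.5,
                           target_gain = 1,
                           calibrate = TRUE,
                           rectify_mode = c("warn", "error")) {
  rectify_mode <- match.arg(rectify_mode)
  if (tau_c <= 0) stop("network_params: 'tau_c' must be > 0")
  if (alpha_cw <= 0 || alpha_ccw <= 0)
    stop("network_params: velocity-tuning slopes must be > 0")
  if (u_cw0 < 0 || u_ccw0 < 0)
    stop("network_params: velocity-neuron baselines must be >= 0")
  grid <- ring_grid(n)
  kernel <- build_recurrent_kernel(n, excit_width, excit_amp, inhib_amp)
  expand <- function(x, what) {
    if (length(x) == 1L) rep(as.numeric(x), n)
    else if (length(x) == n) as.numeric(x)
    else stop(sprintf("network_params: '%s' must be scalar or length n", what))
  }
  Wv_mod <- expand(Wv_mod, "Wv_mod")
  if (any(Wv_mod <= 0)) stop("network_params: 'Wv_mod' must be positive")
  if (is.null(w_cw_c)) w_cw_c <- w_rot_c
  if (is.null(w_ccw_c)) w_ccw_c <- w_rot_c
  p <- structure(list(
    grid = grid, kernel = kernel, tau_c = tau_c,
    g_c_rot = g_c_rot,
    w_cw_c = expand(w_cw_c, "w_cw_c"),
    w_ccw_c = expand(w_ccw_c, "w_ccw_c"),
    b_bins = as.integer(b_bins),
    b = as.integer(b_bins) * grid$dpsi,
    u_cw0 = u_cw0, u_ccw0 = u_ccw0,
    alpha_cw = alpha_cw, alpha_ccw = alpha_ccw,
    Wv_cw = Wv_mod, Wv_ccw = Wv_mod,
    i_margin = i_margin,
    cc_gain = cc_gain, I_tonic = I_tonic, gamma_inh = gamma_inh,
    vis_amp = vis_amp,
    rectify_mode = rectify_mode
  ), class = "network_params")
  p <- refresh_precomp(p)
  # Rest-state templates: converged bumps with peak at angle 0
  p <- compute_templates(p)
  if (calibrate) {
    gp <- compute_pi_gain_profile(p)
    k0 <- spatial_average(gp)
    if (!is.finite(k0) || k0 <= 0)
      stop("network_params: calibration failed; rest-state gain is not positive")
    sc <- target_gain / k0
    p$Wv_cw <- p$Wv_cw * sc
    p$Wv_ccw <- p$Wv_ccw * sc
    p <- refresh_precomp(p)
    p <- compute_templates(p)  # margin unchanged, but keep templates in sync
  }
  p$gain_profile <- compute_pi_gain_profile(p)
  p
}

#' @export
print.network_params <- function(x, ...) {
  cat(sprintf("<network_params> n = %d, tau_c = %g s, offset b = %d bin(s)\n",
              x$grid$n, x$tau_c, x$b_bins))
  if (!is.null(x$gain_profile))
    cat(sprintf("  PI gain: k0 = %.4f (range %.4f .. %.4f)\n",
                spatial_average(x$gain_profile),
                min(x$gain_profile$k_values), max(x$gain_profile$k_values)))
  invisible(x)
}

# Precompute the dense kernel matrix and the presynaptic index maps used by
# the stepping routines.
refresh_precomp <- function(p) {
  n <- p$grid$n
  m <- p$b_bins
  jj <- seq_len(n) - 1L
  p$precomp <- list(
    Wm = kernel_matrix(p$kernel),
    # central neuron j listens to CCW-ring neuron j - m and CW-ring j + m
    idx_ccw = ((jj - m) %% n) + 1L,
    idx_cw = ((jj + m) %% n) + 1L
  )
  p
}

# Rotation-ring rates given central rates and velocity (instantaneous).
rotation_ring_rates <- function(r_c, v, params, Wv_cw = params$Wv_cw,
                                Wv_ccw = params$Wv_ccw) {
  u <- velocity_neuron_rates(v, params)
  base_cw <- Wv_cw * params$u_cw0
  base_ccw <- Wv_ccw * params$u_ccw0
  r_cw <- pmax(params$g_c_rot * r_c + Wv_cw * u$cw -
                 (base_cw + params$i_margin), 0)
  r_ccw <- pmax(params$g_c_rot * r_c + Wv_ccw * u$ccw -
                  (base_ccw + params$i_margin), 0)
  list(cw = r_cw, ccw = r_ccw)
}

#' Network state container
#'
#' Firing-rate vectors of all ring populations at one time point.
#'
#' @param r_c,r_cw,r_ccw Nonnegative rate vectors (Hz) over the ring grid.
#' @param t Time (seconds).
#' @return An object of class `network_state`.
#' @export
network_state <- function(r_c, r_cw = NULL, r_ccw = NULL, t = 0) {
  if (any(r_c < 0)) stop("network_state: rates must be nonnegative")
  n <- length(r_c)
  if (is.null(r_cw)) r_cw <- numeric(n)
  if (is.null(r_ccw)) r_ccw <- numeric(n)
  structure(list(r_c = r_c, r_cw = r_cw, r_ccw = r_ccw, t = t),
            class = "network_state")
}

#' Visual drive specification
#'
#' A bump-shaped current injected into the central ring, peaked at the
#' landmark-defined position `theta_star`.
#'
#' @param theta_star Peak location (radians).
#' @param active Logical; when `FALSE` no current is injected (landmarks
#'   extinguished).
#' @return An object of class `visual_drive`.
#' @export
visual_drive <- function(theta_star = 0, active = TRUE) {
  structure(list(theta_star = wrap_2pi(theta_star), active = active),
            class = "visual_drive")
}

# Visual current vector: the stored profile rho_vis (peak at angle 0)
# rotated to theta_star by nearest-bin shift.
visual_current <- function(visual, params) {
  if (is.null(visual) || !isTRUE(visual$active)) return(numeric(params$grid$n))
  shift <- round(visual$theta_star / params$grid$dpsi)
  circ_shift(params$rho_vis, shift)
}

#' One explicit-Euler step of the central ring alone
#'
#' Integrates `tau_c * dr/dt = -r + relu(W_cc conv r + I_ext)` for one time
#' step. This is the isolated bump-attractor dynamics; the full model adds
#' rotation-ring feedback and visual input through [step_full_network()].
#'
#' @param state A `network_state` (only `r_c` is used).
#' @param I_ext External input current vector (may be zero).
#' @param dt Time step (seconds); must be positive and at most `tau_c / 10`.
#' @param params A `network_params` object.
#' @return The updated `network_state` with `t` advanced by `dt`.
#' @export
step_central_ring <- function(state, I_ext, dt, params) {
  if (dt <= 0 || dt > params$tau_c)
    stop("step_central_ring: 'dt' must be in (0, tau_c]")
  if (dt > params$tau_c / 10)
    stop("step_central_ring: 'dt' must be at most tau_c / 10 for stability")
  r <- state$r_c
  drive <- pmax(params$precomp$Wm %*% r + I_ext, 0)
  state$r_c <- as.numeric(r + dt / params$tau_c * (-r + drive))
  state$t <- state$t + dt
  state
}

#' One explicit-Euler step of the full ring attractor
#'
#' Velocity neurons are evaluated at `v`, rotation rings follow their
#' inputs instantaneously, and the central ring is advanced one Euler step
#' under recurrent, rotation-ring and (optionally) visual input.
#'
#' @param state A `network_state`.
#' @param v Animal velocity (rad/s, counter-clockwise positive).
#' @param visual A [visual_drive()] or `NULL`.
#' @param dt Time step (seconds, at most `tau_c / 10`).
#' @param params A `network_params` object.
#' @return The updated `network_state` (with refreshed rotation-ring rates).
#' @export
step_full_network <- function(state, v, visual, dt, params) {
  if (dt <= 0 || dt > params$tau_c / 10)
    stop("step_full_network: 'dt' must be in (0, tau_c / 10]")
  rot <- rotation_ring_rates(state$r_c, v, params)
  pc <- params$precomp
  I_rot <- params$w_cw_c[pc$idx_cw] * rot$cw[pc$idx_cw] +
    params$w_ccw_c[pc$idx_ccw] * rot$ccw[pc$idx_ccw]
  I_ext <- I_rot + visual_current(visual, params) + params$I_tonic -
    params$gamma_inh * (mean(rot$cw) + mean(rot$ccw))
  r <- state$r_c
  drive <- pmax(params$cc_gain * (pc$Wm %*% r) + I_ext, 0)
  state$r_c <- as.numeric(r + dt / params$tau_c * (-r + drive))
  state$r_cw <- rot$cw
  state$r_ccw <- rot$ccw
  state$t <- state$t + dt
  state
}

#' Population-vector decoding of the bump location
#'
#' Circular mean of the neuron angles weighted by firing rate:
#' `atan2(sum(r * sin(psi)), sum(r * cos(psi)))`, mapped to `[0, 2*pi)`.
#'
#' @param rates Nonnegative rate vector.
#' @param grid The `ring_grid` the rates live on.
#' @return Decoded angle in `[0, 2*pi)`.
#' @export
decode_bump_location <- function(rates, grid) {
  if (all(rates == 0)) stop("decode_bump_location: no bump (all rates zero)")
  wrap_2pi(atan2(sum(rates * sin(grid$angles)), sum(rates * cos(grid$angles))))
}

# Relax the full network at rest (v = 0, no visual) to its equilibrium
# bump, starting from a cosine bump at theta0.
relax_to_bump <- function(params, theta0 = 0, dt = params$tau_c / 20,
                          t_max = 2, tol = 1e-10) {
  n <- params$grid$n
  r <- 40 * pmax(cos(wrap_angle(params$grid$angles - theta0)), 0)
  st <- network_state(r)
  steps <- ceiling(t_max / dt)
  for (i in seq_len(steps)) {
    r_old <- st$r_c
    st <- step_full_network(st, 0, NULL, dt, params)
    if (max(abs(st$r_c - r_old)) < tol * max(st$r_c)) break
  }
  st
}

# Store rest-state templates (peak rotated to angle 0) and the visual
# profile derived from the bump shape.
compute_templates <- function(p) {
  st <- relax_to_bump(p, theta0 = 0)
  th <- decode_bump_location(st$r_c, p$grid)
  shift <- -round(th / p$grid$dpsi)
  p$rc_template <- circ_shift(st$r_c, shift)
  p$rcw_template <- circ_shift(st$r_cw, shift)
  p$rccw_template <- circ_shift(st$r_ccw, shift)
  p$rho_vis <- p$vis_amp * max(p$rc_template) *
    p$rc_template / max(p$rc_template)
  p
}

#' Simulate the isolated central ring
#'
#' Runs [step_central_ring()] from a given or random initial rate vector.
#' Used to demonstrate bump emergence from unstructured activity.
#'
#' @param params A `network_params`.
#' @param r0 Initial rate vector, or `NULL` to draw uniform random rates.
#' @param duration Simulated time (seconds).
#' @param dt Time step (seconds).
#' @param I_ext Constant external input vector (default zero).
#' @param seed Seed for the random initial condition.
#' @param r0_max Upper bound of the uniform random initial rates.
#' @param record_every Record the rate vector every this many steps
#'   (0 = final state only).
#' @return List with `state` (final `network_state`), and if recording,
#'   `times` and `rates` (matrix, one row per record).
#' @export
simulate_central_ring <- function(params, r0 = NULL, duration = 0.1,
                                  dt = params$tau_c / 20, I_ext = NULL,
                                  seed = 1L, r0_max = 10,
                                  record_every = 0L) {
  n <- params$grid$n
  if (is.null(r0)) {
    set.seed(seed)
    r0 <- stats::runif(n, 0, r0_max)
  }
  if (is.null(I_ext)) I_ext <- numeric(n)
  st <- network_state(r0)
  steps <- ceiling(duration / dt)
  rec_t <- c(); rec_r <- NULL
  if (record_every > 0L) rec_r <- matrix(NA_real_, 0, n)
  for (i in seq_len(steps)) {
    st <- step_central_ring(st, I_ext, dt, params)
    if (record_every > 0L && i %% record_every == 0L) {
      rec_t <- c(rec_t, st$t)
      rec_r <- rbind(rec_r, st$r_c)
    }
  }
  out <- list(state = st)
  if (record_every > 0L) { out$times <- rec_t; out$rates <- rec_r }
  out
}

# Smoothed single-bump test: circular moving average, then count local
# maxima that rise above `rel_height` of the global peak (transient
# sub-percent ripples do not count as competing bumps).
is_single_bump <- function(r, smooth_bins = NULL, rel_height = 0.2) {
  n <- length(r)
  if (is.null(smooth_bins)) smooth_bins <- max(3L, round(n / 32))
  w <- rep(1 / smooth_bins, smooth_bins)
  # circular moving average via padding
  pad <- c(r[(n - smooth_bins + 1L):n], r, r[1L:smooth_bins])
  s <- stats::filter(pad, w, sides = 2)
  s <- as.numeric(s[(smooth_bins + 1L):(smooth_bins + n)])
  if (max(s) <= 0) return(FALSE)
  up <- s > circ_shift(s, 1L)
  dn <- s >= circ_shift(s, -1L)
  n_peaks <- sum(up & dn & s > rel_height * max(s))
  amp_ok <- (max(s) - min(s)) > 0.5 * max(s)
  n_peaks == 1L && amp_ok
}

#' Time to bump emergence from random initial activity
#'
#' Simulates the isolated central ring from seeded uniform random rates and
#' reports the first time at which the (circularly smoothed) rate vector
#' has exactly one local maximum and a dominant amplitude, i.e. a single
#' activity bump has formed.
#'
#' @inheritParams simulate_central_ring
#' @param t_max Give up after this much simulated time (seconds).
#' @return Emergence time in seconds (or `NA` if no bump formed by `t_max`).
#' @export
bump_emergence_time <- function(params, dt = params$tau_c / 20, seed = 1L,
                                t_max = 0.5, r0_max = 10) {
  n <- params$grid$n
  set.seed(seed)
  st <- network_state(stats::runif(n, 0, r0_max))
  I0 <- numeric(n)
  steps <- ceiling(t_max / dt)
  for (i in seq_len(steps)) {
    st <- step_central_ring(st, I0, dt, params)
    if (is_single_bump(st$r_c)) return(st$t)
  }
  NA_real_
}

#' Simulate the full ring attractor network
#'
#' Advances the full three-ring model under a velocity profile and an
#' optional visual-landmark protocol. The landmark-defined position
#' `theta_star` is integrated as `d theta_star / dt = k_star * v`
#' (continuing silently during landmark-off intervals); the visual current
#' is injected only while landmarks are on.
#'
#' @param params A `network_params`.
#' @param velocity A [velocity_profile], a function of time, or a constant.
#' @param visual A [visual_protocol], or `NULL` for no visual input.
#' @param duration Simulated time (seconds).
#' @param dt Integrator time step (seconds).
#' @param record_dt Sampling interval of the returned trajectory (seconds).
#' @param theta0 Initial bump location (radians).
#' @param theta_star0 Initial landmark position (radians).
#' @param state Optional initial `network_state` (overrides `theta0`).
#' @return A `trajectory` data frame with columns `t`, `v`, `theta`
#'   (decoded bump location), `theta_star`, `theta_tilde` (wrapped
#'   positional error), `landmarks_on`, `mean_rc`, `mean_rcw`, `mean_rccw`.
#'   The final `network_state` is attached as attribute `"final_state"`.
#' @export
simulate_network <- function(params, velocity = 0, visual = NULL,
                             duration = 1, dt = params$tau_c / 20,
                             record_dt = 0.01, theta0 = 0, theta_star0 = theta0,
                             state = NULL) {
  vfun <- as_velocity_function(velocity)
  if (is.null(state)) {
    state <- relax_to_bump(params, theta0)
    state$t <- 0
  }
  steps <- ceiling(duration / dt)
  rec_every <- max(1L, round(record_dt / dt))
  n_rec <- floor(steps / rec_every) + 1L
  out <- data.frame(t = numeric(n_rec), v = numeric(n_rec),
                    theta = numeric(n_rec), theta_star = numeric(n_rec),
                    theta_tilde = numeric(n_rec),
                    landmarks_on = logical(n_rec),
                    mean_rc = numeric(n_rec), mean_rcw = numeric(n_rec),
                    mean_rccw = numeric(n_rec))
  theta_star <- wrap_2pi(theta_star0)
  record <- function(k, t, v, on) {
    th <- decode_bump_location(state$r_c, params$grid)
    out$t[k] <<- t; out$v[k] <<- v
    out$theta[k] <<- th
    out$theta_star[k] <<- theta_star
    out$theta_tilde[k] <<- wrap_angle(theta_star - th)
    out$landmarks_on[k] <<- on
    out$mean_rc[k] <<- mean(state$r_c)
    out$mean_rcw[k] <<- mean(state$r_cw)
    out$mean_rccw[k] <<- mean(state$r_ccw)
  }
  rot0 <- rotation_ring_rates(state$r_c, vfun(0), params)
  state$r_cw <- rot0$cw; state$r_ccw <- rot0$ccw
  on0 <- if (is.null(visual)) FALSE else landmarks_on_at(visual, 0)
  record(1L, 0, vfun(0), on0)
  k <- 1L
  for (i in seq_len(steps)) {
    t_now <- (i - 1L) * dt
    v <- vfun(t_now)
    on <- FALSE
    vis <- NULL
    if (!is.null(visual)) {
      ks <- k_star_at(visual, t_now)
      theta_star <- wrap_2pi(theta_star + ks * v * dt)
      on <- landmarks_on_at(visual, t_now)
      if (on) vis <- visual_drive(theta_star, TRUE)
    }
    state <- step_full_network(state, v, vis, dt, params)
    if (i %% rec_every == 0L) {
      k <- k + 1L
      record(k, state$t, v, on)
    }
  }
  out <- out[seq_len(k), ]
  class(out) <- c("trajectory", "data.frame")
  attr(out, "final_state") <- state
  attr(out, "dt") <- dt
  out
}

# Accept a velocity_profile, a function, or a constant.
as_velocity_function <- function(velocity) {
  if (inherits(velocity, "velocity_profile")) {
    function(t) velocity_at(velocity, t)
  } else if (is.function(velocity)) {
    velocity
  } else if (is.numeric(velocity) && length(velocity) == 1L) {
    function(t) velocity
  } else stop("cannot interpret 'velocity'")
}
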