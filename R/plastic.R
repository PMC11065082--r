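#' Parameters of the modified (plastic) ring attractor
#'
#' The modified model replaces the direct visual-to-central drive of the
#' classical ring attractor with three structural changes that together
#' let the network recalibrate its path-integration gain:
#'
#' 1. An *association ring* between the visual ring and the attractor:
#'    it receives weak, hardwired topographic input from the central ring
#'    and plastic input from the visual ring (`W_vis_assoc`, a full
#'    matrix). After Hebbian training its activity is strongly visually
#'    driven and acts as the landmark-position proxy.
#' 2. *Offset inhibitory connections* from the association ring onto the
#'    rotation rings (CCW offset onto the CCW ring, CW offset onto the CW
#'    ring). Combined with topographic central-ring excitation this is the
#'    error-rate-code wiring: each rotation ring varies its firing rate
#'    monotonically with the positional error (CCW up, CW down), and the
#'    differential rates both correct the error (a virtual velocity
#'    signal) and teach the plastic velocity weights.
#' 3. *Plastic velocity-to-rotation weights* `W_v_cw`, `W_v_ccw`
#'    (per-neuron vectors, bounded in `[0, w_max]`) updated by a
#'    covariance-style Hebbian rule: presynaptic deviation of the velocity
#'    neurons from baseline times postsynaptic deviation of the rotation
#'    ring from its aligned-at-rest baseline, with slow decay. Baseline
#'    subtraction makes immobility with zero error produce no drift.
#'
#' Inhibition onto each rotation ring tracks its own ring's plastic
#' baseline drive (`W_v * u0 + i_margin`), so the attractor stays balanced
#' at rest while the weights change; the gain is carried entirely by the
#' velocity-deviation pathway, as in the base model.
#'
#' The constructor builds a base [network_params()] at size `n`, attaches
#' the association machinery, and then numerically calibrates the initial
#' velocity-weight scale so the measured path-integration gain equals
#' `target_gain` (the analytic calibration of the base model does not see
#' the association-ring sculpting of the rotation bumps, so the plastic
#' model is calibrated against its own probe).
#'
#' @param n Neurons per ring (default 96; plastic protocols run long
#'   simulated times, so a coarser ring than the base model's default
#'   keeps them affordable).
#' @param o_bins Offset (whole bins) of the association-to-rotation
#'   inhibitory connections; sets the slope of the error-rate code.
#' @param g_ca Weak hardwired central-to-association weight.
#' @param g_ar Association-to-rotation inhibitory weight.
#' @param ar_spread Spatial spread (radians) of the divergent
#'   association-to-rotation inhibition. The spread makes the inhibition
#'   act on a rotation ring as a smoothly graded level rather than a
#'   sharp bump, so that a positional error modulates the ring's activity
#'   nearly uniformly over its footprint -- the same way the velocity
#'   input does -- and the differential rotation rates push the central
#'   bump toward the landmarks (error correction) while still encoding
#'   the error in their mean rates.
#' @param I_a0 Constant inhibition on the association ring (Hz).
#' @param tau_a Association-ring time constant (seconds).
#' @param R_vis Peak rate of the visual ring's bump (Hz).
#' @param vis_width Width (radians) of the visual bump.
#' @param wa_peak Peak of the trained visual-to-association weight band.
#' @param wa_width Width (radians) of the trained band.
#' @param wa_max Bound on visual-to-association weights.
#' @param lr_assoc Learning rate of visual-association plasticity (1/s).
#' @param decay_assoc Weight decay of the association matrix (1/s).
#' @param lr_w Learning rate of velocity-weight plasticity
#'   (weight per Hz^2 second).
#' @param decay_w Velocity-weight decay rate (1/s), or `NULL` (default)
#'   to calibrate it homeostatically at construction: the decay is set so
#'   that the veridical condition (`k_star = 1`, constant running speed
#'   `v_ref`) produces no net drift of the mean velocity weight. The
#'   rotation rings' rates are modulated by velocity as well as by error,
#'   so the raw Hebbian update carries a velocity-squared potentiation
#'   bias even with landmarks veridical; the calibrated decay absorbs
#'   that bias, and recalibration is then driven by the deviation of the
#'   positional error from its veridical operating point.
#' @param w_max Bound on the velocity weights (multiple of the calibrated
#'   initial weight).
#' @param v_ref Reference running speed (rad/s) for the homeostatic decay
#'   calibration.
#' @param target_gain Initial path-integration gain after calibration.
#' @param ... Passed to [network_params()] (e.g. `tau_c`, kernel shape).
#' @return An object of class `plastic_params` (extends `network_params`).
#' @export
plastic_params <- function(n = 96, o_bins = 10L,
                           g_ca = 0.1, g_ar = 1.5, ar_spread = 0.5,
                           I_a0 = 5,
                           tau_a = 0.01, R_vis = 30, vis_width = 0.4,
                           wa_peak = 1.2, wa_width = 0.3, wa_max = 2.5,
                           lr_assoc = 0.3, decay_assoc = 0.1,
                           lr_w = 3e-4, decay_w = NULL, w_max = 4,
                           v_ref = 0.3, target_gain = 1, ...) {
  base <- network_params(n = n, calibrate = TRUE,
                         target_gain = target_gain, ...)
  p <- base
  p$o_bins <- as.integer(o_bins)
  p$g_ca <- g_ca; p$g_ar <- g_ar; p$ar_spread <- ar_spread
  p$I_a0 <- I_a0
  p$tau_a <- tau_a
  p$R_vis <- R_vis; p$vis_width <- vis_width
  p$wa_peak <- wa_peak; p$wa_width <- wa_width; p$wa_max <- wa_max
  p$lr_assoc <- lr_assoc; p$decay_assoc <- decay_assoc
  p$lr_w <- lr_w; p$decay_w <- 0
  p$vis_template <- R_vis * gauss_bump(p$grid, vis_width)
  # per-neuron visual-weight budget = one row of the trained band
  p$wa_row_budget <- wa_peak * sum(gauss_bump(p$grid, wa_width))
  # circulant matrix of the normalized inhibition-spread kernel
  spread <- gauss_bump(p$grid, ar_spread)
  spread <- spread / (sum(spread) * p$grid$dpsi)
  kern <- structure(list(values = spread, grid = p$grid,
                         is_rotation_invariant = TRUE, scale = 1),
                    class = "weight_kernel")
  p$precomp$Sa <- kernel_matrix(kern)
  class(p) <- c("plastic_params", "network_params")
  p <- plastic_templates(p)
  # probe-based calibration of the initial velocity-weight scale
  for (i in 1:2) {
    k_meas <- estimate_pi_gain(plastic_state(p), p, probe_v = 0.5)
    p$Wv_cw <- p$Wv_cw * target_gain / k_meas
    p$Wv_ccw <- p$Wv_ccw * target_gain / k_meas
    p <- plastic_templates(p)
  }
  p$w_max_abs <- w_max * mean(p$Wv_cw)
  if (is.null(decay_w)) {
    # homeostatic calibration: make the veridical condition stationary
    st <- plastic_state(p)
    dt <- p$tau_c / 10
    for (i in seq_len(round(5 / dt)))      # settle into the moving state
      st <- step_plastic_network(st, v_ref, dt, p, k_star = 1)
    w0 <- mean(c(st$W_v_cw, st$W_v_ccw))
    for (i in seq_len(round(15 / dt)))
      st <- step_plastic_network(st, v_ref, dt, p, k_star = 1,
                                 plastic_w = TRUE)
    w1 <- mean(c(st$W_v_cw, st$W_v_ccw))
    p$decay_w <- log(w1 / w0) / 15
  } else {
    p$decay_w <- decay_w
  }
  p
}

# Unit-peak wrapped-Gaussian bump centered at angle 0.
gauss_bump <- function(grid, width) {
  d <- wrap_angle(grid$angles)
  exp(-d^2 / (2 * width^2))
}

#' Idealized trained visual-to-association weight matrix
#'
#' Constructs the weight matrix that Hebbian association training
#' converges to: a diagonal band linking visual neurons to association
#' neurons at the same angle (synthetic stand-in for a training run; see
#' [train_association()] for learning it from activity).
#'
#' @param params A `plastic_params`.
#' @return An `n x n` nonnegative matrix (rows = association/post,
#'   columns = visual/pre).
#' @export
make_trained_association <- function(params) {
  g <- params$grid
  d <- outer(g$angles, g$angles, function(a, b) wrap_angle(a - b))
  params$wa_peak * exp(-d^2 / (2 * params$wa_width^2))
}

#' State of the plastic network
#'
#' Extends the base network state with the association-ring rates and the
#' plastic weights.
#'
#' @param params A `plastic_params`.
#' @param theta0 Initial bump location (radians).
#' @param theta_star0 Initial landmark position (radians).
#' @param W_vis_assoc Visual-to-association matrix; default the trained
#'   band from [make_trained_association()].
#' @param W_v_cw,W_v_ccw Initial velocity weights; default the calibrated
#'   uniform profiles in `params`.
#' @return An object of class `plastic_state`.
#' @export
plastic_state <- function(params, theta0 = 0, theta_star0 = theta0,
                          W_vis_assoc = NULL,
                          W_v_cw = params$Wv_cw, W_v_ccw = params$Wv_ccw) {
  if (is.null(W_vis_assoc)) W_vis_assoc <- make_trained_association(params)
  sh <- round(theta0 / params$grid$dpsi)
  st <- structure(list(
    r_c = circ_shift(params$rc_template, sh),
    r_cw = circ_shift(params$rcw_template, sh),
    r_ccw = circ_shift(params$rccw_template, sh),
    r_a = circ_shift(params$ra_template, sh),
    theta_star = wrap_2pi(theta_star0),
    W_vis_assoc = pmin(pmax(W_vis_assoc, 0), params$wa_max),
    W_v_cw = W_v_cw, W_v_ccw = W_v_ccw,
    t = 0), class = c("plastic_state", "network_state"))
  st
}

# Rotation-ring rates of the plastic model: topographic central
# excitation, velocity-deviation drive through the plastic weights,
# margin gating, and offset inhibition from the association ring.
plastic_rotation_rates <- function(r_c, r_a, v, W_v_cw, W_v_ccw, params) {
  o <- params$o_bins
  dev_cw <- -params$alpha_cw * v
  dev_ccw <- params$alpha_ccw * v
  ra_s <- as.numeric(params$precomp$Sa %*% r_a)  # divergent inhibition
  inh_ccw <- params$g_ar * circ_shift(ra_s, o)   # CCW offset
  inh_cw <- params$g_ar * circ_shift(ra_s, -o)   # CW offset
  list(
    cw = pmax(params$g_c_rot * r_c + W_v_cw * dev_cw -
                params$i_margin - inh_cw, 0),
    ccw = pmax(params$g_c_rot * r_c + W_v_ccw * dev_ccw -
                 params$i_margin - inh_ccw, 0)
  )
}

# Aligned rest-state templates of the plastic network (landmarks on,
# theta_star = theta = 0, v = 0), plus the rotation baselines used for
# Hebbian baseline subtraction.
plastic_templates <- function(p) {
  n <- p$grid$n
  st <- list(r_c = circ_shift(p$rc_template, 0),
             r_a = numeric(n))
  W <- make_trained_association(p)
  r_vis <- p$vis_template
  dt <- p$tau_c / 10
  for (i in seq_len(400L)) {
    rot <- plastic_rotation_rates(st$r_c, st$r_a, 0, p$Wv_cw, p$Wv_ccw, p)
    I_rot <- rot_feedback(rot, p)
    drive_c <- pmax(p$cc_gain * (p$precomp$Wm %*% st$r_c) + I_rot +
                      p$I_tonic -
                      p$gamma_inh * (mean(rot$cw) + mean(rot$ccw)), 0)
    drive_a <- pmax((W %*% r_vis) * p$grid$dpsi + p$g_ca * st$r_c -
                      p$I_a0, 0)
    st$r_c <- as.numeric(st$r_c + dt / p$tau_c * (-st$r_c + drive_c))
    st$r_a <- as.numeric(st$r_a + dt / p$tau_a * (-st$r_a + drive_a))
  }
  th <- decode_bump_location(st$r_c, p$grid)
  sh <- -round(th / p$grid$dpsi)
  p$rc_template <- circ_shift(st$r_c, sh)
  p$ra_template <- circ_shift(st$r_a, sh)
  rot <- plastic_rotation_rates(p$rc_template, p$ra_template, 0,
                                p$Wv_cw, p$Wv_ccw, p)
  p$rcw_template <- rot$cw
  p$rccw_template <- rot$ccw
  p
}

# Offset rotation-to-central feedback (shared with the base model wiring).
rot_feedback <- function(rot, params) {
  pc <- params$precomp
  params$w_cw_c[pc$idx_cw] * rot$cw[pc$idx_cw] +
    params$w_ccw_c[pc$idx_ccw] * rot$ccw[pc$idx_ccw]
}

#' One step of the plastic ring attractor
#'
#' Advances central and association rings one Euler step, refreshes the
#' (instantaneous) rotation rings, moves the landmark position
#' `theta_star` by `k_star * v * dt`, and applies the enabled Hebbian
#' updates.
#'
#' @param state A `plastic_state`.
#' @param v Velocity (rad/s).
#' @param dt Time step (seconds).
#' @param params A `plastic_params`.
#' @param k_star Visual gain moving the landmarks.
#' @param landmarks_on Logical; when `FALSE` the visual ring is silent.
#' @param plastic_w Enable velocity-weight plasticity.
#' @param plastic_assoc Enable visual-association plasticity.
#' @return The updated `plastic_state`.
#' @export
step_plastic_network <- function(state, v, dt, params, k_star = 1,
                                 landmarks_on = TRUE,
                                 plastic_w = FALSE,
                                 plastic_assoc = FALSE) {
  state$theta_star <- wrap_2pi(state$theta_star + k_star * v * dt)
  r_vis <- if (landmarks_on) {
    circ_shift(params$vis_template,
               round(state$theta_star / params$grid$dpsi))
  } else numeric(params$grid$n)
  rot <- plastic_rotation_rates(state$r_c, state$r_a, v,
                                state$W_v_cw, state$W_v_ccw, params)
  I_rot <- rot_feedback(rot, params)
  drive_c <- pmax(params$cc_gain * (params$precomp$Wm %*% state$r_c) +
                    I_rot + params$I_tonic -
                    params$gamma_inh * (mean(rot$cw) + mean(rot$ccw)), 0)
  drive_a <- pmax((state$W_vis_assoc %*% r_vis) * params$grid$dpsi +
                    params$g_ca * state$r_c - params$I_a0, 0)
  if (plastic_w) {
    theta_dec <- decode_bump_location(state$r_c, params$grid)
    sh <- round(theta_dec / params$grid$dpsi)
    base_cw <- circ_shift(params$rcw_template, sh)
    base_ccw <- circ_shift(params$rccw_template, sh)
    state$W_v_cw <- clip01(state$W_v_cw + dt *
      (params$lr_w * (-params$alpha_cw * v) * (rot$cw - base_cw) -
         params$decay_w * state$W_v_cw), params$w_max_abs)
    state$W_v_ccw <- clip01(state$W_v_ccw + dt *
      (params$lr_w * (params$alpha_ccw * v) * (rot$ccw - base_ccw) -
         params$decay_w * state$W_v_ccw), params$w_max_abs)
  }
  if (plastic_assoc) {
    state$W_vis_assoc <- assoc_hebb(state$W_vis_assoc, state$r_a, r_vis,
                                    params, dt)
  }
  state$r_c <- as.numeric(state$r_c +
                            dt / params$tau_c * (-state$r_c + drive_c))
  state$r_a <- as.numeric(state$r_a +
                            dt / params$tau_a * (-state$r_a + drive_a))
  state$r_cw <- rot$cw
  state$r_ccw <- rot$ccw
  state$t <- state$t + dt
  state
}

clip01 <- function(x, hi) pmin(pmax(x, 0), hi)

# Covariance-style Hebbian update of the visual-to-association matrix
# with synaptic scaling: the postsynaptic factor is the association
# rate's deviation from its population mean, so synapses onto neurons
# outside the active bump are depressed while the coactive (diagonal)
# ones potentiate -- without the depression the band broadens a little
# with every pairing and eventually smears. Each association neuron's
# total visual weight is additionally capped at the trained-band budget.
assoc_hebb <- function(W, r_a, r_vis, params, dt) {
  post <- r_a - mean(r_a)
  # saturation gating: neurons whose total visual weight has reached the
  # budget stop potentiating (a redistributive rescaling would instead
  # keep reshaping saturated rows toward whichever positions were paired
  # last, leaving a recency-biased, lumpy map)
  gate <- rowSums(W) < params$wa_row_budget
  post <- post * gate
  W <- pmin(pmax(
    W + dt * (params$lr_assoc * outer(post, r_vis) * params$grid$dpsi -
                params$decay_assoc * W),
    0), params$wa_max)
  W
}

#' Estimate the path-integration gain by a landmark-extinction probe
#'
#' Freezes plasticity, silences the visual ring, drives the network at a
#' constant probe velocity, and measures the bump's total (unwrapped)
#' displacement per unit commanded displacement:
#' `gain = delta theta / (probe_v * probe_T)`, after discarding a settling
#' transient. The probe should cover at least one full lap so that any
#' spatial inhomogeneity of the gain averages out; if it covers less, the
#' estimate is flagged (`attr(., "partial_lap")`). Note that a
#' displacement-per-time probe weights each location by the time spent
#' there, so for a strongly inhomogeneous gain profile it is biased
#' towards the low-gain regions; use [measure_gain_profile()] and average
#' over locations when the arithmetic spatial mean is wanted.
#'
#' @param state A `plastic_state` snapshot (not modified).
#' @param params A `plastic_params`.
#' @param probe_v Probe velocity (rad/s), nonzero.
#' @param probe_T Probe duration (seconds); default one nominal lap.
#' @param dt Time step.
#' @param transient Settling time discarded before measuring (seconds).
#' @return The dimensionless gain estimate, with attribute
#'   `"partial_lap"` (TRUE if the probe covered less than one lap).
#' @export
estimate_pi_gain <- function(state, params, probe_v = 0.5,
                             probe_T = 2 * pi / abs(probe_v),
                             dt = params$tau_c / 10, transient = 0.5) {
  if (probe_v == 0) stop("estimate_pi_gain: 'probe_v' must be nonzero")
  st <- state
  steps <- ceiling((transient + probe_T) / dt)
  n_rec <- steps + 1L
  th <- numeric(n_rec)
  th[1L] <- decode_bump_location(st$r_c, params$grid)
  for (i in seq_len(steps)) {
    st <- step_plastic_network(st, probe_v, dt, params,
                               landmarks_on = FALSE)
    th[i + 1L] <- decode_bump_location(st$r_c, params$grid)
  }
  thu <- unwrap_angles(th)
  i0 <- max(1L, round(transient / dt))
  dth <- thu[n_rec] - thu[i0]
  dT <- (n_rec - i0) * dt
  gain <- dth / (probe_v * dT)
  attr(gain, "partial_lap") <- abs(dth) < 2 * pi
  gain
}

#' Error-rate-code wiring
#'
#' The generic three-population connectivity that converts a difference in
#' two bump locations into a firing-rate code: population X3 receives
#' topographic excitation from X1 and offset inhibition from X2. With a
#' CCW offset, X3's mean rate increases monotonically with the CCW
#' difference `x2 - x1`; a CW offset reverses the direction.
#'
#' @param offset Offset magnitude in radians (0 < offset < pi/2); rounded
#'   to whole bins of `n`.
#' @param direction `"ccw"` or `"cw"`.
#' @param n Ring size the wiring operates on.
#' @param g_excit,g_inhib Pathway gains.
#' @param threshold Constant inhibition subtracted before rectification.
#' @return An object of class `error_code_wiring`.
#' @export
build_error_code_wiring <- function(offset, direction = c("ccw", "cw"),
                                    n = 96, g_excit = 1, g_inhib = 1,
                                    threshold = 0) {
  direction <- match.arg(direction)
  if (offset <= 0 || offset >= pi / 2)
    stop("build_error_code_wiring: 'offset' must lie in (0, pi/2)")
  grid <- ring_grid(n)
  o_bins <- max(1L, round(offset / grid$dpsi))
  structure(list(grid = grid, o_bins = o_bins, direction = direction,
                 offset = o_bins * grid$dpsi,
                 g_excit = g_excit, g_inhib = g_inhib,
                 threshold = threshold),
            class = "error_code_wiring")
}

#' @describeIn build_error_code_wiring Response of the X3 population to
#'   bump activities `x1` (excitatory) and `x2` (inhibitory).
#' @param wiring An `error_code_wiring`.
#' @param x1,x2 Rate vectors of the excitatory and inhibitory source
#'   populations.
#' @export
error_code_response <- function(wiring, x1, x2) {
  sh <- if (wiring$direction == "ccw") wiring$o_bins else -wiring$o_bins
  pmax(wiring$g_excit * x1 - wiring$g_inhib * circ_shift(x2, sh) -
         wiring$threshold, 0)
}

#' Hebbian update of the visual-association weights
#'
#' Single plasticity step on the full visual-to-association matrix:
#' potentiation proportional to the product of postsynaptic
#' (association-ring) and presynaptic (visual-ring) rates, with weight
#' decay and clipping to `[0, wa_max]`. Thin wrapper around the update
#' embedded in [step_plastic_network()], exposed for direct use.
#'
#' @param state A `plastic_state`.
#' @param r_vis Visual-ring rate vector (zero while landmarks are off).
#' @param params A `plastic_params`.
#' @param dt Time step (seconds).
#' @return The state with updated `W_vis_assoc`.
#' @export
hebbian_update_visual_association <- function(state, r_vis, params, dt) {
  state$W_vis_assoc <- assoc_hebb(state$W_vis_assoc, state$r_a, r_vis,
                                  params, dt)
  state
}

#' Hebbian update of the plastic velocity weights
#'
#' Single covariance-style plasticity step on the velocity-to-rotation
#' weights: presynaptic deviation of the velocity neurons from baseline
#' (`-alpha_cw * v` for CW, `+alpha_ccw * v` for CCW) times postsynaptic
#' deviation of the rotation-ring rates from their aligned-at-rest
#' baseline, minus decay; clipped to `[0, w_max]`. Exposed for direct
#' use; [step_plastic_network()] applies the same update when
#' `plastic_w = TRUE`.
#'
#' @param state A `plastic_state` (rotation rates must be current).
#' @param v Velocity (rad/s).
#' @param params A `plastic_params`.
#' @param dt Time step (seconds).
#' @return The state with updated `W_v_cw`, `W_v_ccw`.
#' @export
hebbian_update_velocity_weights <- function(state, v, params, dt) {
  theta_dec <- decode_bump_location(state$r_c, params$grid)
  sh <- round(theta_dec / params$grid$dpsi)
  base_cw <- circ_shift(params$rcw_template, sh)
  base_ccw <- circ_shift(params$rccw_template, sh)
  state$W_v_cw <- clip01(state$W_v_cw + dt *
    (params$lr_w * (-params$alpha_cw * v) * (state$r_cw - base_cw) -
       params$decay_w * state$W_v_cw), params$w_max_abs)
  state$W_v_ccw <- clip01(state$W_v_ccw + dt *
    (params$lr_w * (params$alpha_ccw * v) * (state$r_ccw - base_ccw) -
       params$decay_w * state$W_v_ccw), params$w_max_abs)
  state
}

#' Train the visual-association mapping from activity
#'
#' Novel-environment phase: starts from small random visual-association
#' weights and pairs the central-ring bump (weak hardwired topographic
#' drive) with the veridical visual bump at a sequence of positions
#' sampled across the track, with association plasticity enabled. At
#' each visited position the aligned coactivation selectively
#' potentiates the visual-to-association synapses linking coding for the
#' same place, carving out the diagonal associative band; synaptic
#' scaling keeps each association neuron's total visual weight bounded.
#' Only the aligned coactivation matters to the Hebbian step, so the
#' training visits positions as stationary episodes (in an experiment
#' the animal reaches them by running laps).
#'
#' @param params A `plastic_params`.
#' @param n_sites Number of training positions per sweep (uniform grid,
#'   shuffled independently each pass).
#' @param passes Number of sweeps over the track.
#' @param dwell Time spent at each position (seconds).
#' @param dt Time step.
#' @param seed Seed for the random initial weights and site order.
#' @param w_init_sd Scale of the random initial weights.
#' @return The trained `plastic_state`.
#' @export
train_association <- function(params, n_sites = 48L, passes = 8L,
                              dwell = 0.25, dt = params$tau_c / 10,
                              seed = 1L, w_init_sd = 0.05) {
  set.seed(seed)
  n <- params$grid$n
  W0 <- matrix(abs(stats::rnorm(n * n, 0, w_init_sd)), n, n)
  st <- plastic_state(params, W_vis_assoc = W0)
  # repeated shuffled sweeps: every position is refreshed well within a
  # weight-decay time, so the learned band is the steady state of
  # potentiation against decay (independent of visit order) rather than
  # a cumulative record dominated by the most recent visits
  sites <- unlist(lapply(seq_len(passes), function(p)
    sample(2 * pi * (seq_len(n_sites) - 1L) / n_sites)))
  steps <- ceiling(dwell / dt)
  for (site in sites) {
    sh <- round(site / params$grid$dpsi)
    st$r_c <- circ_shift(params$rc_template, sh)
    st$r_a <- circ_shift(params$ra_template, sh)
    st$theta_star <- wrap_2pi(site)
    for (i in seq_len(steps)) {
      st <- step_plastic_network(st, 0, dt, params, k_star = 1,
                                 landmarks_on = TRUE,
                                 plastic_w = FALSE, plastic_assoc = TRUE)
    }
  }
  st
}

#' Run the gain-recalibration protocol
#'
#' Reproduces the landmark-manipulation experiment on the plastic
#' network: the animal runs while the landmarks are moved with visual
#' gain `k_star`; velocity-weight plasticity is enabled while landmarks
#' are on. Every `probe_every` seconds the landmarks are extinguished and
#' the path-integration gain is measured with a frozen-plasticity probe
#' ([estimate_pi_gain()]); the recalibration phase then resumes.
#'
#' @param params A `plastic_params`.
#' @param k_star Visual gain of the manipulation.
#' @param duration Total recalibration time, excluding probes (seconds).
#' @param velocity Running speed: constant, function, or
#'   [velocity_profile].
#' @param probe_every Interval between gain probes (seconds).
#' @param probe_v Probe velocity (rad/s).
#' @param dt Time step.
#' @param state Optional starting `plastic_state` (default: trained
#'   association, calibrated weights).
#' @param record_dt Sampling interval of the returned trajectory.
#' @return List with `gains` (data frame: `t`, `gain`), `trajectory`
#'   (t, v, theta, theta_star, theta_tilde, mean rates, mean weights),
#'   `final_gain`, `initial_gain`, and `state`.
#' @export
run_recalibration_protocol <- function(params, k_star, duration = 120,
                                       velocity = 0.3, probe_every = 30,
                                       probe_v = 0.5,
                                       dt = params$tau_c / 10,
                                       state = NULL, record_dt = 0.1) {
  vfun <- as_velocity_function(velocity)
  if (is.null(state)) state <- plastic_state(params)
  g0 <- estimate_pi_gain(state, params, probe_v = probe_v)
  gains <- data.frame(t = 0, gain = as.numeric(g0))
  steps <- ceiling(duration / dt)
  rec_every <- max(1L, round(record_dt / dt))
  probe_steps <- max(1L, round(probe_every / dt))
  n_rec <- floor(steps / rec_every) + 1L
  traj <- data.frame(t = numeric(n_rec), v = numeric(n_rec),
                     theta = numeric(n_rec), theta_star = numeric(n_rec),
                     theta_tilde = numeric(n_rec),
                     mean_rcw = numeric(n_rec), mean_rccw = numeric(n_rec),
                     mean_wv_cw = numeric(n_rec),
                     mean_wv_ccw = numeric(n_rec))
  ri <- 0L
  for (i in seq_len(steps)) {
    v <- vfun((i - 1L) * dt)
    state <- step_plastic_network(state, v, dt, params, k_star = k_star,
                                  landmarks_on = TRUE, plastic_w = TRUE)
    if (i %% rec_every == 0L || i == 1L) {
      ri <- ri + 1L
      th <- decode_bump_location(state$r_c, params$grid)
      traj[ri, ] <- c(state$t, v, th, state$theta_star,
                      wrap_angle(state$theta_star - th),
                      mean(state$r_cw), mean(state$r_ccw),
                      mean(state$W_v_cw), mean(state$W_v_ccw))
    }
    if (i %% probe_steps == 0L) {
      g <- estimate_pi_gain(state, params, probe_v = probe_v)
      gains <- rbind(gains, data.frame(t = state$t, gain = as.numeric(g)))
    }
  }
  g_end <- estimate_pi_gain(state, params, probe_v = probe_v)
  gains <- rbind(gains, data.frame(t = state$t, gain = as.numeric(g_end)))
  traj <- traj[seq_len(ri), ]
  class(traj) <- c("trajectory", "data.frame")
  list(gains = gains, trajectory = traj,
       initial_gain = gains$gain[1L],
       final_gain = gains$gain[nrow(gains)],
       state = state)
}

#' Run the landmark error-correction protocol
#'
#' With a trained association ring and plasticity frozen, an abrupt
#' misalignment is introduced between the attractor's bump and the
#' landmark position; the offset association-to-rotation connections
#' convert the error into differential rotation-ring rates (a virtual
#' velocity signal) that re-align the central bump with the landmarks.
#'
#' @param params A `plastic_params`.
#' @param initial_offset Imposed error `theta_star - theta` (radians).
#' @param duration Simulated time (seconds).
#' @param dt Time step.
#' @param record_dt Sampling interval.
#' @return A `trajectory` data frame (t, theta, theta_star, theta_tilde,
#'   mean_rcw, mean_rccw).
#' @export
run_error_correction_protocol <- function(params, initial_offset,
                                          duration = 3,
                                          dt = params$tau_c / 10,
                                          record_dt = 0.01) {
  state <- plastic_state(params, theta0 = 0,
                         theta_star0 = initial_offset)
  steps <- ceiling(duration / dt)
  rec_every <- max(1L, round(record_dt / dt))
  n_rec <- floor(steps / rec_every) + 1L
  out <- data.frame(t = numeric(n_rec), theta = numeric(n_rec),
                    theta_star = numeric(n_rec),
                    theta_tilde = numeric(n_rec),
                    mean_rcw = numeric(n_rec), mean_rccw = numeric(n_rec))
  th <- decode_bump_location(state$r_c, params$grid)
  out[1L, ] <- c(0, th, state$theta_star,
                 wrap_angle(state$theta_star - th),
                 mean(state$r_cw), mean(state$r_ccw))
  ri <- 1L
  for (i in seq_len(steps)) {
    state <- step_plastic_network(state, 0, dt, params, k_star = 1,
                                  landmarks_on = TRUE)
    if (i %% rec_every == 0L) {
      ri <- ri + 1L
      th <- decode_bump_location(state$r_c, params$grid)
      out[ri, ] <- c(state$t, th, state$theta_star,
                     wrap_angle(state$theta_star - th),
                     mean(state$r_cw), mean(state$r_ccw))
    }
  }
  out <- out[seq_len(ri), ]
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Rotation-ring tuning to imposed positional error
#'
#' Tuning-curve probe of the error-rate code: for each imposed error the
#' landmark position is clamped at `theta + error`, the network relaxes
#' briefly, and the mean rotation-ring rates are recorded.
#'
#' @param params A `plastic_params`.
#' @param errors Vector of imposed errors (radians).
#' @param settle Relaxation time per point (seconds).
#' @param dt Time step.
#' @return Data frame with `error`, `mean_rcw`, `mean_rccw`.
#' @export
error_tuning_curve <- function(params, errors = seq(-0.4, 0.4,
                                                    length.out = 17),
                               settle = 0.3, dt = params$tau_c / 10) {
  out <- data.frame(error = errors, mean_rcw = NA_real_,
                    mean_rccw = NA_real_)
  for (i in seq_along(errors)) {
    st <- plastic_state(params, theta0 = 0, theta_star0 = errors[i])
    steps <- ceiling(settle / dt)
    for (s in seq_len(steps)) {
      # clamp the landmark at a fixed error relative to the current bump
      th <- decode_bump_location(st$r_c, params$grid)
      st$theta_star <- wrap_2pi(th + errors[i])
      st <- step_plastic_network(st, 0, dt, params, k_star = 0,
                                 landmarks_on = TRUE)
    }
    out$mean_rcw[i] <- mean(st$r_cw)
    out$mean_rccw[i] <- mean(st$r_ccw)
  }
  out
}
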