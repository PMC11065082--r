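#' Adaptive gain-update rules
#'
#' A gain rule is a pluggable map `g0(k0, theta_tilde, v)` giving the rate
#' of change of the spatial-average path-integration gain `k0` as a
#' function of the current gain, the wrapped positional error and the
#' animal's velocity. The package provides the standard examples:
#'
#' * `gain_rule_linear(mu)`: `g0 = mu * theta_tilde * v`. The simplest
#'   rule; it changes the gain in the direction of the error-velocity
#'   product and has slope `mu > 0` with respect to that product, so it
#'   satisfies both the necessary sign condition for complete
#'   recalibration and the sufficient slope condition.
#' * `gain_rule_velocity_biased(mu, eta)`:
#'   `g0 = mu * (eta * k0 * v^2 + theta_tilde * v)`. Mirrors the plastic
#'   network, whose error code in the rotation rings is additionally
#'   modulated by velocity; the `v^2` bias makes recalibration partial:
#'   the rule's zero sits at `theta_tilde = -eta * k0 * v` rather than at
#'   zero error, so a nonzero steady-state positional error (and gain
#'   error) remains. With `eta = 0` it reduces to the linear rule.
#' * `gain_rule_cubic(mu)`: `g0 = mu * (theta_tilde * v)^3`. Satisfies the
#'   sign (necessary) condition but has zero slope at the origin, so it
#'   fails the sufficient condition.
#' * `gain_rule_sign_flipped(mu)`: `g0 = -mu * theta_tilde * v`. Violates
#'   the necessary condition; gain errors grow instead of shrinking.
#'
#' @param g0 Function `(k0, theta_tilde, v) -> d k0 / dt` (1/s).
#' @param label Short human-readable label.
#' @param params Named list of the rule's parameters.
#' @return An object of class `gain_rule`.
#' @export
gain_rule <- function(g0, label = "custom", params = list()) {
  stopifnot(is.function(g0))
  structure(list(g0 = g0, label = label, params = params),
            class = "gain_rule")
}

#' @export
print.gain_rule <- function(x, ...) {
  ps <- if (length(x$params))
    paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", ")
  else ""
  cat(sprintf("<gain_rule> %s  (%s)\n", x$label, ps))
  invisible(x)
}

#' @rdname gain_rule
#' @param mu Positive learning rate.
#' @export
gain_rule_linear <- function(mu) {
  if (mu <= 0) stop("gain_rule_linear: 'mu' must be > 0")
  force(mu)
  gain_rule(function(k0, theta_tilde, v) mu * theta_tilde * v,
            label = "linear", params = list(mu = mu))
}

#' @rdname gain_rule
#' @param eta Velocity-bias constant (dimensioned so `eta * k0 * v^2`
#'   matches `theta_tilde * v`, i.e. seconds per radian-free units).
#' @export
gain_rule_velocity_biased <- function(mu, eta) {
  if (mu <= 0) stop("gain_rule_velocity_biased: 'mu' must be > 0")
  force(mu); force(eta)
  gain_rule(function(k0, theta_tilde, v)
    mu * (eta * k0 * v^2 + theta_tilde * v),
    label = "velocity-biased", params = list(mu = mu, eta = eta))
}

#' @rdname gain_rule
#' @export
gain_rule_cubic <- function(mu) {
  if (mu <= 0) stop("gain_rule_cubic: 'mu' must be > 0")
  force(mu)
  gain_rule(function(k0, theta_tilde, v) mu * (theta_tilde * v)^3,
            label = "cubic", params = list(mu = mu))
}

#' @rdname gain_rule
#' @export
gain_rule_sign_flipped <- function(mu) {
  if (mu <= 0) stop("gain_rule_sign_flipped: 'mu' must be > 0")
  force(mu)
  gain_rule(function(k0, theta_tilde, v) -mu * theta_tilde * v,
            label = "sign-flipped", params = list(mu = mu))
}

#' One step of the error dynamics
#'
#' Advances the error-coordinate form of the reduced model,
#' \deqn{d\tilde\theta/dt = -\beta(\tilde\theta) + \tilde{k} v -
#'       k_{ac}(\theta) v, \quad d\tilde{k}/dt = -g_0(k_0, \tilde\theta, v)}
#' where `theta_tilde = theta_star - theta` is the wrapped positional
#' error and `k_tilde = k_star - k0` the gain error. Under the change of
#' variables this is the same flow as [simulate_reduced()] with a constant
#' visual gain.
#'
#' @param state List (or `error_state`) with `theta_tilde`, `k_tilde`.
#' @param v Velocity (rad/s).
#' @param beta A [feedback_function].
#' @param kac_at_theta Gain deviation `kac(theta)` at the current bump
#'   location (scalar; 0 for a homogeneous gain).
#' @param rule A [gain_rule].
#' @param k0 Current spatial-average gain (passed to the rule).
#' @param dt Time step (seconds).
#' @param method `"rk4"` or `"euler"`.
#' @return Updated state list with `theta_tilde` wrapped to `(-pi, pi]`.
#' @export
error_dynamics_step <- function(state, v, beta, kac_at_theta, rule, k0, dt,
                                method = c("rk4", "euler")) {
  method <- match.arg(method)
  if (dt <= 0 || dt > 0.5 / beta$amplitude)
    stop("error_dynamics_step: 'dt' must be positive and small relative to the feedback rate")
  bfun <- beta$fun
  derivs <- function(tt, kt) {
    c(-bfun(wrap_angle(tt)) + kt * v - kac_at_theta * v,
      -rule$g0(k0, wrap_angle(tt), v))
  }
  tt <- state$theta_tilde
  kt <- state$k_tilde
  if (method == "euler") {
    d <- derivs(tt, kt)
    tt <- tt + dt * d[1L]; kt <- kt + dt * d[2L]
  } else {
    k1 <- derivs(tt, kt)
    k2 <- derivs(tt + dt / 2 * k1[1L], kt + dt / 2 * k1[2L])
    k3 <- derivs(tt + dt / 2 * k2[1L], kt + dt / 2 * k2[2L])
    k4 <- derivs(tt + dt * k3[1L], kt + dt * k3[2L])
    incr <- (k1 + 2 * k2 + 2 * k3 + k4) / 6
    tt <- tt + dt * incr[1L]; kt <- kt + dt * incr[2L]
  }
  list(theta_tilde = wrap_angle(tt), k_tilde = kt)
}

#' Simulate the error dynamics at constant velocity
#'
#' Convenience wrapper around [error_dynamics_step()]; `k0` is carried
#' along as `k_star - k_tilde`.
#'
#' @inheritParams error_dynamics_step
#' @param theta_tilde0,k_tilde0 Initial errors.
#' @param k_star Visual gain (used only to reconstruct `k0` for the rule).
#' @param duration Simulated time (seconds).
#' @param record_dt Sampling interval.
#' @return A data frame with `t`, `theta_tilde`, `k_tilde`, `k0`.
#' @export
simulate_error_dynamics <- function(theta_tilde0, k_tilde0, v, beta, rule,
                                    k_star = 1.5, kac_at_theta = 0,
                                    duration = 600, dt = 0.01,
                                    record_dt = 0.5,
                                    method = c("rk4", "euler")) {
  method <- match.arg(method)
  st <- list(theta_tilde = theta_tilde0, k_tilde = k_tilde0)
  steps <- ceiling(duration / dt)
  rec_every <- max(1L, round(record_dt / dt))
  n_rec <- floor(steps / rec_every) + 1L
  out <- data.frame(t = numeric(n_rec), theta_tilde = numeric(n_rec),
                    k_tilde = numeric(n_rec), k0 = numeric(n_rec))
  out[1L, ] <- c(0, st$theta_tilde, st$k_tilde, k_star - st$k_tilde)
  ri <- 1L
  for (s in seq_len(steps)) {
    st <- error_dynamics_step(st, v, beta, kac_at_theta, rule,
                              k0 = k_star - st$k_tilde, dt, method = method)
    if (s %% rec_every == 0L) {
      ri <- ri + 1L
      out[ri, ] <- c(s * dt, st$theta_tilde, st$k_tilde,
                     k_star - st$k_tilde)
    }
  }
  out[seq_len(ri), ]
}

#' Check the necessary sign condition for gain recalibration
#'
#' A gain rule can recalibrate the average gain only if it updates the
#' gain in the direction of the product of velocity and the deviation of
#' the positional error from its steady-state value:
#' `sign(g0) == sign((theta_tilde - theta_tilde_inf) * v)` in a
#' neighbourhood of `theta_tilde_inf` (complete recalibration corresponds
#' to `theta_tilde_inf = 0`). The check evaluates the rule on a grid and
#' reports any sign mismatches.
#'
#' @param rule A [gain_rule].
#' @param v_values Velocity grid (must exclude 0).
#' @param theta_tilde_inf Steady-state positional error (0 for the
#'   complete-recalibration form of the condition).
#' @param k0 Gain at which the rule is probed.
#' @param half_width Half-width (radians) of the error neighbourhood.
#' @param n_grid Number of error grid points (the point exactly at
#'   `theta_tilde_inf` is removed).
#' @return List with `pass`, `n_fail`, `failures` (data frame of
#'   mismatching grid points), and the grid metadata.
#' @export
check_necessary_condition <- function(rule, v_values,
                                      theta_tilde_inf = 0, k0 = 1,
                                      half_width = 0.5, n_grid = 21L) {
  if (any(v_values == 0))
    stop("check_necessary_condition: 'v_values' must exclude 0")
  tt <- theta_tilde_inf + seq(-half_width, half_width, length.out = n_grid)
  tt <- tt[tt != theta_tilde_inf]
  grid <- expand.grid(theta_tilde = tt, v = v_values)
  g <- mapply(rule$g0, k0, grid$theta_tilde, grid$v)
  want <- sign((grid$theta_tilde - theta_tilde_inf) * grid$v)
  ok <- sign(g) == want
  list(pass = all(ok), n_fail = sum(!ok),
       failures = grid[!ok, , drop = FALSE],
       theta_tilde_inf = theta_tilde_inf, k0 = k0,
       half_width = half_width, n_grid = n_grid)
}

#' Check the sufficient slope condition for gain recalibration
#'
#' A rule passing the necessary sign condition is guaranteed to
#' recalibrate (completely or partially) if in addition its slope with
#' respect to the error-velocity product is positive at the rule's zero:
#' `d g0 / d(theta_tilde * v) > 0` evaluated where
#' `g0(k0, theta_tilde, v0) = 0`. The slope is estimated by a central
#' difference in `theta_tilde` divided by `v0`.
#'
#' @param rule A [gain_rule].
#' @param v0 Probe velocity (nonzero).
#' @param k0 Gain at which the rule is probed.
#' @param h Central-difference step (radians).
#' @param tol Positivity tolerance (1/s).
#' @return List with `pass`, `slope`, `theta_tilde_zero` (the zero of the
#'   rule where the slope was taken), `v0`.
#' @export
check_sufficient_condition <- function(rule, v0, k0 = 1, h = 1e-4,
                                       tol = 1e-8) {
  if (v0 == 0) stop("check_sufficient_condition: 'v0' must be nonzero")
  f <- function(tt) rule$g0(k0, tt, v0)
  tz <- 0
  if (abs(f(0)) > 1e-14) {
    lo <- -pi / 2; hi <- pi / 2
    if (f(lo) * f(hi) < 0) {
      tz <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    }
  }
  slope <- (f(tz + h) - f(tz - h)) / (2 * h) / v0
  list(pass = is.finite(slope) && slope > tol, slope = slope,
       theta_tilde_zero = tz, v0 = v0)
}

#' Full condition report for a gain rule
#'
#' Runs the complete-recalibration necessary condition, the generalized
#' necessary condition around an empirically estimated steady-state error,
#' and the sufficient slope condition, and bundles the results. The
#' steady-state error `theta_tilde_inf` is estimated by simulating the
#' error dynamics at constant `v0` and taking the circular mean of the
#' positional error over the trailing 10 percent of the run.
#'
#' @inheritParams check_necessary_condition
#' @param v0 Constant velocity for the steady-state estimate and slope
#'   check.
#' @param beta Feedback function used in the steady-state simulation.
#' @param k_star Visual gain of the steady-state simulation.
#' @param duration Length of the steady-state simulation (seconds).
#' @return An object of class `condition_report`.
#' @export
check_gain_rule <- function(rule, v0 = 1,
                            v_values = c(-1, -0.5, 0.5, 1),
                            beta = beta_sinusoidal(0.66), k_star = 1.5,
                            k0 = 1, duration = 1200,
                            half_width = 0.5, n_grid = 21L) {
  nec <- check_necessary_condition(rule, v_values, theta_tilde_inf = 0,
                                   k0 = k0, half_width = half_width,
                                   n_grid = n_grid)
  sim <- simulate_error_dynamics(0, k_star - k0, v0, beta, rule,
                                 k_star = k_star, duration = duration)
  tail_idx <- sim$t >= 0.9 * max(sim$t)
  tt_inf <- circular_mean(sim$theta_tilde[tail_idx])
  # The generalized condition is derived for constant velocity: the
  # steady-state error (and the rule's zero) depend on v and on the
  # recalibrated gain, so it is probed at v0 and the steady-state k0.
  k0_inf <- k_star - sim$k_tilde[nrow(sim)]
  nec_gen <- check_necessary_condition(rule, v_values = v0,
                                       theta_tilde_inf = tt_inf,
                                       k0 = k0_inf,
                                       half_width = half_width,
                                       n_grid = n_grid)
  suf <- check_sufficient_condition(rule, v0, k0 = k0)
  structure(list(label = rule$label,
                 necessary_complete = nec,
                 necessary_generalized = nec_gen,
                 sufficient_slope = suf,
                 theta_tilde_inf = tt_inf,
                 k_tilde_final = sim$k_tilde[nrow(sim)],
                 v0 = v0, k_star = k_star),
            class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  pf <- function(z) if (isTRUE(z$pass)) "PASS" else "fail"
  cat(sprintf("<condition_report> rule: %s\n", x$label))
  cat(sprintf("  necessary (complete, tt_inf = 0):      %s\n",
              pf(x$necessary_complete)))
  cat(sprintf("  necessary (generalized, tt_inf = %.4f): %s\n",
              x$theta_tilde_inf, pf(x$necessary_generalized)))
  cat(sprintf("  sufficient slope: %s (slope = %.4g /s at zero %.4f)\n",
              pf(x$sufficient_slope), x$sufficient_slope$slope,
              x$sufficient_slope$theta_tilde_zero))
  invisible(x)
}

#' Serialize a condition report to JSON
#'
#' @param report A `condition_report`.
#' @param path Optional file path; when given, writes and returns the
#'   path invisibly.
#' @return JSON string (or the path, invisibly).
#' @export
condition_report_json <- function(report, path = NULL) {
  x <- list(
    label = report$label,
    necessary_complete = report$necessary_complete$pass,
    necessary_generalized = report$necessary_generalized$pass,
    sufficient_slope = report$sufficient_slope$pass,
    slope = report$sufficient_slope$slope,
    theta_tilde_inf = report$theta_tilde_inf,
    k_tilde_final = report$k_tilde_final,
    v0 = report$v0, k_star = report$k_star
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(path))
  }
  js
}

# Circular mean of wrapped angles.
circular_mean <- function(x) {
  atan2(mean(sin(x)), mean(cos(x)))
}

#' Mechanistic monotonicity probes on a trajectory
#'
#' Examines which trajectory variables carry a rate code of the positional
#' error, as required mechanistically for gain recalibration: (a) the
#' instantaneous regime -- Spearman rank correlation between each rotation
#' ring's mean firing rate and the instantaneous positional error
#' `theta_tilde`; (b) the integral regime -- rank correlation between slow
#' variables (the gain estimate, or mean synaptic weights if present) and
#' the running time-integral of `theta_tilde`. A shuffled-time permutation
#' control reports the correlation magnitude expected by chance.
#'
#' @param traj A trajectory data frame with column `theta_tilde`; columns
#'   `mean_rcw`/`mean_rccw` enable the instantaneous probes, `k0` (or
#'   `gain`) the integral probe.
#' @param n_perm Number of time-shuffle permutations for the control.
#' @param seed Seed for the permutation control.
#' @param min_rows Minimum trajectory length.
#' @return An object of class `probe_report`: list of probe results, each
#'   with the observed rho, the sign, and the permutation quantiles.
#' @export
mechanistic_probe_report <- function(traj, n_perm = 200L, seed = 1L,
                                     min_rows = 50L) {
  if (nrow(traj) < min_rows)
    stop("mechanistic_probe_report: trajectory too short")
  set.seed(seed)
  tt <- traj$theta_tilde
  probes <- list()
  perm_ctrl <- function(x, y) {
    r <- vapply(seq_len(n_perm), function(i)
      stats::cor(sample(x), y, method = "spearman"), numeric(1))
    stats::quantile(abs(r), c(0.5, 0.95), names = FALSE)
  }
  add_probe <- function(name, x, y) {
    rho <- stats::cor(x, y, method = "spearman")
    q <- perm_ctrl(x, y)
    probes[[name]] <<- list(rho = rho, sign = sign(rho),
                            perm_median_abs = q[1L],
                            perm_q95_abs = q[2L])
  }
  if (!is.null(traj$mean_rccw)) add_probe("ccw_rate_vs_error", tt, traj$mean_rccw)
  if (!is.null(traj$mean_rcw)) add_probe("cw_rate_vs_error", tt, traj$mean_rcw)
  int_err <- cumsum(tt) * stats::median(diff(traj$t))
  slow <- traj$k0
  if (is.null(slow)) slow <- traj$gain
  if (!is.null(slow)) add_probe("slow_var_vs_integral_error", int_err, slow)
  structure(list(probes = probes, n = nrow(traj), n_perm = n_perm),
            class = "probe_report")
}

#' @export
print.probe_report <- function(x, ...) {
  cat(sprintf("<probe_report> %d samples, %d permutations\n", x$n, x$n_perm))
  for (nm in names(x$probes)) {
    p <- x$probes[[nm]]
    cat(sprintf("  %-28s rho = %+0.3f (perm |rho| q95 = %.3f)\n",
                nm, p$rho, p$perm_q95_abs))
  }
  invisible(x)
}
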