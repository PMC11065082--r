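# Shared, lazily built fixtures. Heavy objects (calibrated parameter sets,
# long reference runs) are constructed once per test session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# Default calibrated base network (n = 256).
base_params <- function() {
  memo("base_params", function() suppressWarnings(network_params()))
}

# Base network with +/-40% sinusoidally modulated velocity weights.
modulated_params <- function() {
  memo("modulated_params", function() {
    suppressWarnings(
      network_params(Wv_mod = 1 + 0.4 * cos(ring_grid(256)$angles)))
  })
}

# Calibrated plastic network (n = 96).
plastic_fixture <- function() {
  memo("plastic_params", function() suppressWarnings(plastic_params()))
}

# Reference recalibration run: linear rule, pause-resume velocity,
# 30 simulated minutes -- the canonical landmark-conflict session used
# by several convergence checks.
fig_run <- function() {
  memo("fig_run", function() {
    vp <- make_velocity_profile("pause_resume", duration = 1800, mean_v = 1)
    simulate_reduced(reduced_state(theta = 0, theta_star = 0, k0 = 1),
                     vp, k_star = 1.5, beta = beta_sinusoidal(0.66),
                     rule = gain_rule_linear(0.02),
                     duration = 1800, dt = 0.01, record_dt = 0.1)
  })
}

# Fractional circular shift by FFT phase ramp (for shape comparisons at
# sub-bin alignment).
frac_shift <- function(x, shift_rad) {
  n <- length(x)
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  Re(stats::fft(stats::fft(x) * exp(-1i * k * shift_rad), inverse = TRUE)) / n
}
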