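test_that("the error-code wiring turns bump misalignment into a rate code", {
  n <- 96
  g <- ring_grid(n)
  wiring <- build_error_code_wiring(0.65, "ccw", n = n, g_excit = 1,
                                    g_inhib = 0.8)
  bump <- function(at) pmax(cos(g$angles - at), 0)
  resp <- function(diff) mean(error_code_response(wiring, bump(0),
                                                  bump(diff)))
  base <- resp(0)
  lo <- resp(-0.4)    # CW difference: inhibition nearer, rate drops
  hi <- resp(0.4)     # CCW difference: inhibition moved away, rate rises
  expect_gt(hi, base)
  expect_lt(lo, base)
  expect_gt(base, lo); expect_lt(base, hi)  # baseline strictly between
  # flipping the offset direction flips the slope
  wcw <- build_error_code_wiring(0.65, "cw", n = n, g_excit = 1,
                                 g_inhib = 0.8)
  respc <- function(diff) mean(error_code_response(wcw, bump(0),
                                                   bump(diff)))
  expect_lt(respc(0.4), respc(0))
  expect_gt(respc(-0.4), respc(0))
  expect_error(build_error_code_wiring(2, "ccw"), "offset")
})

test_that("rotation rings are monotonically tuned to the positional error", {
  p <- plastic_fixture()
  tc <- error_tuning_curve(p)
  expect_gt(cor(tc$error, tc$mean_rccw, method = "spearman"), 0.95)
  expect_lt(cor(tc$error, tc$mean_rcw, method = "spearman"), -0.95)
  # mirror symmetry of the push-pull pair
  expect_equal(tc$mean_rcw, rev(tc$mean_rccw), tolerance = 0.05)
})

test_that("landmarks correct an abrupt positional error via rotation rates", {
  p <- plastic_fixture()
  # no offset: nothing happens
  ec0 <- run_error_correction_protocol(p, 0, duration = 1)
  expect_lt(max(abs(ec0$theta_tilde)), 0.02)
  expect_lt(diff(range(ec0$mean_rccw - ec0$mean_rcw)), 0.05)
  # CCW offset: CCW ring rate above CW, error is eliminated
  ec <- run_error_correction_protocol(p, 0.5, duration = 3)
  expect_equal(ec$theta_tilde[1], 0.5, tolerance = 0.05)
  expect_lt(abs(tail(ec$theta_tilde, 1)), 0.05)
  early <- ec$t > 0.05 & ec$t < 0.5
  expect_true(all(ec$mean_rccw[early] > ec$mean_rcw[early]))
})

test_that("hebbian velocity updates vanish at rest with zero error", {
  p <- plastic_fixture()
  st <- plastic_state(p)
  st2 <- step_plastic_network(st, 0, 1e-3, p, plastic_w = TRUE)
  # decay is the only drift; with one step it is below 1e-6 relative
  expect_equal(mean(st2$W_v_cw), mean(st$W_v_cw) *
                 (1 - p$decay_w * 1e-3), tolerance = 1e-8)
  expect_equal(mean(st2$W_v_ccw), mean(st$W_v_ccw) *
                 (1 - p$decay_w * 1e-3), tolerance = 1e-8)
})

test_that("sustained positive error times velocity potentiates both weight pools", {
  p <- plastic_fixture()
  st <- plastic_state(p)
  # clamp a CCW error while the animal runs: theta_tilde * v > 0
  dt <- 1e-3
  w_cw0 <- mean(st$W_v_cw); w_ccw0 <- mean(st$W_v_ccw)
  for (i in 1:1000) {
    th <- decode_bump_location(st$r_c, p$grid)
    st$theta_star <- wrap_2pi(th + 0.3)
    st <- step_plastic_network(st, 0.3, dt, p, k_star = 0,
                               plastic_w = TRUE)
  }
  dk_cw <- mean(st$W_v_cw) - w_cw0 + p$decay_w * w_cw0 * 1
  dk_ccw <- mean(st$W_v_ccw) - w_ccw0 + p$decay_w * w_ccw0 * 1
  expect_gt(dk_cw, 0)
  expect_gt(dk_ccw, 0)
})

test_that("hebbian association learning carves out the diagonal band", {
  p <- plastic_fixture()
  st <- train_association(p, seed = 2)
  W <- st$W_vis_assoc
  n <- p$grid$n
  d <- outer(p$grid$angles, p$grid$angles,
             function(a, b) abs(wrap_angle(a - b)))
  on_diag <- mean(W[d < 0.3])
  off_diag <- mean(W[d > 1.0])
  expect_gt(on_diag, 3 * off_diag)
  # visual input is silent: no potentiation term survives
  st_probe <- st
  W_before <- st_probe$W_vis_assoc
  st_probe <- hebbian_update_visual_association(
    st_probe, numeric(n), p, dt = 0.01)
  expect_true(all(st_probe$W_vis_assoc <= W_before + 1e-12))
  expect_equal(st_probe$W_vis_assoc, W_before,
               tolerance = 2 * p$decay_assoc * 0.01)
  # after training, the association ring is visually driven: its
  # response through the learned weights alone tracks the landmark
  # position all around the track
  errs <- vapply(seq(0, 2 * pi, length.out = 25)[-25], function(ts) {
    r_vis <- circ_shift(p$vis_template, round(ts / p$grid$dpsi))
    ra <- pmax(as.numeric(W %*% r_vis) * p$grid$dpsi - p$I_a0, 0)
    abs(wrap_angle(decode_bump_location(ra, p$grid) - wrap_2pi(ts)))
  }, numeric(1))
  expect_lt(median(errs), 0.05)
  expect_lt(max(errs), 0.2)
})

test_that("the landmark-extinction probe recovers a known constant gain", {
  # closed-form check on the pure integrator: displacement over commanded
  # displacement is exactly the gain
  tr <- simulate_reduced(reduced_state(theta = 0, k0 = 0.83),
                         velocity = 0.5, k_star = 1,
                         beta = beta_sinusoidal(0.66),
                         duration = 12, dt = 0.005,
                         landmarks_off_after = 0, record_dt = 0.1)
  th <- unwrap_angles(tr$theta)
  gain <- (th[length(th)] - th[1]) / (0.5 * (tr$t[length(th)] - tr$t[1]))
  expect_equal(gain, 0.83, tolerance = 1e-6)
  # and on the plastic network the probe flags less-than-a-lap coverage
  p <- plastic_fixture()
  g_short <- estimate_pi_gain(plastic_state(p), p, probe_v = 0.5,
                              probe_T = 3)
  expect_true(attr(g_short, "partial_lap"))
  expect_error(estimate_pi_gain(plastic_state(p), p, probe_v = 0), "probe_v")
})

test_that("lap-measured local gains average to the analytic spatial mean", {
  # the uniform-in-theta average of measured local gains is the empirical
  # counterpart of the profile's spatial average (a displacement-per-time
  # probe would instead time-weight the low-gain regions)
  pm <- modulated_params()
  mp <- measure_gain_profile(pm, v = 0.5)
  expect_equal(mean(mp$k_measured), spatial_average(pm$gain_profile),
               tolerance = 0.05)
})

test_that("rates and weights stay bounded through a recalibration run", {
  p <- plastic_fixture()
  rr <- run_recalibration_protocol(p, k_star = 1.3, duration = 60,
                                   probe_every = 60)
  st <- rr$state
  expect_true(all(is.finite(st$r_c)) && max(st$r_c) < 500)
  expect_true(all(st$W_v_cw >= 0 & st$W_v_cw <= p$w_max_abs))
  expect_true(all(st$W_v_ccw >= 0 & st$W_v_ccw <= p$w_max_abs))
  expect_true(all(abs(rr$trajectory$theta_tilde) < pi))
})
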