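test_that("silent network with no input stays silent", {
  p <- base_params()
  st <- network_state(numeric(256))
  st <- step_central_ring(st, numeric(256), 5e-4, p)
  expect_true(all(st$r_c == 0))
})

test_that("time step validation enforces stability bounds", {
  p <- base_params()
  st <- network_state(numeric(256))
  expect_error(step_central_ring(st, numeric(256), -1e-3, p), "dt")
  expect_error(step_central_ring(st, numeric(256), 2 * p$tau_c, p), "dt")
  expect_error(step_central_ring(st, numeric(256), p$tau_c / 2, p), "dt")
  expect_error(step_full_network(st, 0, NULL, p$tau_c / 2, p), "dt")
})

test_that("a single bump emerges from random rates within 100 ms", {
  p <- base_params()
  for (seed in 1:3) {
    t_emerge <- bump_emergence_time(p, dt = 5e-4, seed = seed)
    expect_false(is.na(t_emerge))
    expect_lte(t_emerge, 0.1)
  }
})

test_that("the converged isolated bump is a fixed point of the rectified map", {
  p <- base_params()
  sim <- simulate_central_ring(p, duration = 1, seed = 3)
  r <- bump_fixed_point(p$kernel, sim$state$r_c)
  res <- sqrt(sum((r - pmax(circular_convolve(p$kernel, r), 0))^2) /
                sum(r^2))
  expect_lt(res, 1e-6)
  # and the Euler-converged state is already close to it
  expect_equal(sim$state$r_c / max(sim$state$r_c), r / max(r),
               tolerance = 0.01)
})

test_that("rates are nonnegative at every step of a full-network run", {
  p <- base_params()
  st <- ringrecal:::relax_to_bump(p, 1)
  ok <- TRUE
  for (i in 1:200) {
    st <- step_full_network(st, 0.8, NULL, 5e-4, p)
    ok <- ok && all(st$r_c >= 0) && all(st$r_cw >= 0) && all(st$r_ccw >= 0)
  }
  expect_true(ok)
})

test_that("population-vector decoding is exact for cosine bumps and equivariant", {
  g <- ring_grid(256)
  bump <- pmax(cos(g$angles - pi / 2), 0)
  expect_equal(decode_bump_location(bump, g), pi / 2, tolerance = 1e-9)
  m <- 37
  expect_equal(decode_bump_location(circ_shift(bump, m), g),
               wrap_2pi(pi / 2 + 2 * pi * m / 256), tolerance = 1e-9)
  expect_error(decode_bump_location(numeric(256), g), "no bump")
})

test_that("decoding a noisy bump stays within 0.02 rad over 100 seeded draws", {
  g <- ring_grid(256)
  bump <- pmax(cos(g$angles - 2), 0)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- bump + runif(256, 0, 0.05 * max(bump))
    abs(wrap_angle(decode_bump_location(noisy, g) - 2))
  }, numeric(1))
  expect_lt(max(errs), 0.02)
})

test_that("bump location is invariant during immobility (symmetric weights)", {
  p <- base_params()
  tr <- simulate_network(p, velocity = 0, duration = 10, record_dt = 0.5)
  th <- unwrap_angles(tr$theta)
  expect_lt(abs(th[length(th)] - th[1]), 0.01)
})

test_that("velocity neurons follow push-pull tuning and rectify with warning", {
  p <- base_params()
  u0 <- velocity_neuron_rates(0, p)
  expect_equal(u0$cw, p$u_cw0)
  expect_equal(u0$ccw, p$u_ccw0)
  u <- velocity_neuron_rates(1, p)
  expect_lt(u$cw, p$u_cw0)
  expect_gt(u$ccw, p$u_ccw0)
  # mirror symmetry with symmetric baselines and slopes
  um <- velocity_neuron_rates(-1, p)
  expect_equal(u$cw, um$ccw)
  expect_equal(u$ccw, um$cw)
  expect_warning(velocity_neuron_rates(10, p), "rectifies")
})

test_that("rotating the initial state rotates the whole decoded trajectory", {
  p <- base_params()
  m <- 64
  st1 <- ringrecal:::relax_to_bump(p, 0)
  st2 <- st1
  st2$r_c <- circ_shift(st1$r_c, m)
  th1 <- th2 <- numeric(40)
  for (i in 1:40) {
    st1 <- step_full_network(st1, 0.7, NULL, 5e-4, p)
    st2 <- step_full_network(st2, 0.7, NULL, 5e-4, p)
    th1[i] <- decode_bump_location(st1$r_c, p$grid)
    th2[i] <- decode_bump_location(st2$r_c, p$grid)
  }
  expect_equal(wrap_angle(th2 - th1 - 2 * pi * m / 256), rep(0, 40),
               tolerance = 1e-9)
})

test_that("the moving bump keeps its shape (ansatz invariance)", {
  p <- base_params()
  tr <- simulate_network(p, velocity = 0.25, duration = 3, record_dt = 0.5)
  st <- attr(tr, "final_state")
  th_end <- decode_bump_location(st$r_c, p$grid)
  template <- p$rc_template
  shifted <- frac_shift(template, th_end)
  rel_rms <- sqrt(mean((st$r_c - shifted)^2)) / sqrt(mean(template^2))
  expect_lt(rel_rms, 0.02)
})

test_that("with landmarks on and no movement the bump is pulled to theta_star", {
  p <- base_params()
  vis <- make_visual_protocol(k_star = 1)
  tr <- simulate_network(p, velocity = 0, visual = vis, duration = 3,
                         record_dt = 0.1, theta0 = 0, theta_star0 = 0.8)
  expect_equal(tr$theta_tilde[1], 0.8, tolerance = 0.02)
  expect_lt(abs(tail(tr$theta_tilde, 1)), 0.05)
})
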