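test_that("sinusoidal feedback has the stated values and sign property", {
  b <- beta_sinusoidal(0.66)
  expect_equal(b$fun(0), 0)
  expect_equal(b$fun(pi / 2), 0.66)
  x <- seq(-3, 3, by = 0.1); x <- x[x != 0]
  expect_true(all(sign(b$fun(x[abs(x) < pi])) == sign(x[abs(x) < pi])))
  expect_error(beta_sinusoidal(-1), "amplitude")
})

test_that("with landmarks off and constant gain the model is a pure integrator", {
  tr <- simulate_reduced(reduced_state(theta = 1, k0 = 1.2),
                         velocity = 0.8, k_star = 1,
                         beta = beta_sinusoidal(0.66),
                         duration = 10, dt = 0.01,
                         landmarks_off_after = 0)
  th <- unwrap_angles(tr$theta)
  expect_equal(th[length(th)] - th[1], 1.2 * 0.8 * 10, tolerance = 1e-9)
  # displacement over commanded displacement recovers the gain exactly
  expect_equal((th[length(th)] - th[1]) / (0.8 * 10), 1.2,
               tolerance = 1e-9)
})

test_that("landmark feedback corrects a standing error when the animal is still", {
  tr <- simulate_reduced(reduced_state(theta = 0, theta_star = 1),
                         velocity = 0, k_star = 1,
                         beta = beta_sinusoidal(0.66),
                         duration = 20, dt = 0.01)
  expect_equal(tr$theta_tilde[1], 1, tolerance = 1e-6)
  expect_lt(abs(tail(tr$theta_tilde, 1)), 1e-4)
  # decay is monotone in magnitude
  expect_true(all(diff(abs(tr$theta_tilde)) <= 1e-12))
})

test_that("reduced integrator agrees with an independent ODE solver", {
  skip_if_not_installed("deSolve")
  mu <- 0.02; amp <- 0.66; v <- 1; ks <- 1.5
  rhs <- function(t, y, parms) {
    tt <- ringrecal::wrap_angle(y[2] - y[1])
    list(c(amp * sin(tt) + y[3] * v, ks * v, mu * tt * v))
  }
  sol <- deSolve::ode(c(0, 0, 1), times = seq(0, 100, by = 0.1), rhs,
                      parms = NULL, method = "lsoda",
                      atol = 1e-10, rtol = 1e-10)
  tr <- simulate_reduced(reduced_state(0, 0, 1), velocity = v,
                         k_star = ks, beta = beta_sinusoidal(amp),
                         rule = gain_rule_linear(mu),
                         duration = 100, dt = 0.01, record_dt = 0.1)
  last <- nrow(sol)
  expect_equal(tail(tr$k0, 1), unname(sol[last, 4]), tolerance = 1e-6)
  expect_equal(tail(tr$theta_tilde, 1),
               unname(wrap_angle(sol[last, 3] - sol[last, 2])),
               tolerance = 1e-6)
})

test_that("a spatially inhomogeneous gain modulates the integration speed", {
  g <- ring_grid(64)
  kac <- structure(list(theta = g$angles,
                        k_values = 1 + 0.4 * cos(g$angles), k0 = 1,
                        kac_values = 0.4 * cos(g$angles)),
                   class = "gain_profile")
  tr <- simulate_reduced(reduced_state(theta = 0, k0 = 1),
                         velocity = 0.5, k_star = 1,
                         beta = beta_sinusoidal(0.66), kac = kac,
                         duration = 2, dt = 0.002,
                         landmarks_off_after = 0, record_dt = 0.01)
  th <- unwrap_angles(tr$theta)
  # starts in the high-gain region: faster than the average gain
  expect_gt(th[length(th)] - th[1], 1 * 0.5 * 2)
})

test_that("the landmark-conflict configuration starts at gain error 0.5", {
  st <- reduced_state(theta = 0, theta_star = 0, k0 = 1)
  expect_identical(1.5 - st$k0, 0.5)
  tr <- fig_run()
  expect_identical(tr$k_star[1] - tr$k0[1], 0.5)
})

test_that("euler and rk4 integrators agree at small dt", {
  a1 <- simulate_reduced(reduced_state(0, 0.5, 1), 0.5, 1.2,
                         beta_sinusoidal(0.66), duration = 5, dt = 1e-3,
                         method = "euler")
  a2 <- simulate_reduced(reduced_state(0, 0.5, 1), 0.5, 1.2,
                         beta_sinusoidal(0.66), duration = 5, dt = 1e-3,
                         method = "rk4")
  expect_equal(tail(a1$theta, 1), tail(a2$theta, 1), tolerance = 1e-3)
})
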