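test_that("the linear rule is the error-velocity product", {
  r <- gain_rule_linear(0.02)
  expect_equal(r$g0(1, 0.1, 1), 0.002)
  expect_equal(r$g0(1, 0, 5), 0)
  tt <- seq(-1, 1, length.out = 21); vv <- seq(-2, 2, length.out = 21)
  grid <- expand.grid(tt = tt, vv = vv)
  expect_true(all(sign(mapply(r$g0, 1, grid$tt, grid$vv)) ==
                    sign(grid$tt * grid$vv)))
  expect_error(gain_rule_linear(0), "mu")
})

test_that("the velocity-biased rule reduces to the linear rule at eta = 0", {
  r0 <- gain_rule_velocity_biased(0.02, 0)
  rl <- gain_rule_linear(0.02)
  grid <- expand.grid(tt = seq(-1, 1, 0.25), vv = seq(-2, 2, 0.5),
                      k0 = c(0.5, 1, 1.7))
  expect_equal(mapply(r0$g0, grid$k0, grid$tt, grid$vv),
               mapply(rl$g0, grid$k0, grid$tt, grid$vv))
  # its slope with respect to the error-velocity product is mu > 0
  suf <- check_sufficient_condition(gain_rule_velocity_biased(0.02, 0.12),
                                    v0 = 1)
  expect_true(suf$pass)
  expect_equal(suf$slope, 0.02, tolerance = 1e-6)
})

test_that("the error-dynamics origin is an equilibrium and needs movement", {
  beta <- beta_sinusoidal(0.66)
  rule <- gain_rule_linear(0.02)
  st <- list(theta_tilde = 0, k_tilde = 0)
  st2 <- error_dynamics_step(st, v = 1, beta, kac_at_theta = 0, rule,
                             k0 = 1, dt = 0.01)
  expect_identical(st2$theta_tilde, 0)
  expect_identical(st2$k_tilde, 0)
  # with v = 0 the gain error never changes under the linear rule
  st <- list(theta_tilde = 0.4, k_tilde = 0.5)
  for (i in 1:50) st <- error_dynamics_step(st, 0, beta, 0, rule, 1, 0.01)
  expect_identical(st$k_tilde, 0.5)
})

test_that("error dynamics match the reduced model under change of variables", {
  beta <- beta_sinusoidal(0.66)
  rule <- gain_rule_linear(0.02)
  v <- 0.8; ks <- 1.5
  tr <- simulate_reduced(reduced_state(0, 0, 1), v, ks, beta, rule,
                         duration = 30, dt = 0.005, record_dt = 30)
  ed <- simulate_error_dynamics(0, 0.5, v, beta, rule, k_star = ks,
                                duration = 30, dt = 0.005, record_dt = 30)
  expect_equal(tail(tr$theta_tilde, 1), tail(ed$theta_tilde, 1),
               tolerance = 1e-9)
  expect_equal(ks - tail(tr$k0, 1), tail(ed$k_tilde, 1), tolerance = 1e-9)
})

test_that("condition checkers classify the canonical rules as stated", {
  crs <- lapply(list(gain_rule_linear(0.02),
                     gain_rule_cubic(0.02),
                     gain_rule_velocity_biased(0.02, 0.12),
                     gain_rule_sign_flipped(0.02)),
                check_gain_rule, duration = 800)
  names(crs) <- vapply(crs, `[[`, "", "label")
  # linear: all three pass
  expect_true(crs$linear$necessary_complete$pass)
  expect_true(crs$linear$necessary_generalized$pass)
  expect_true(crs$linear$sufficient_slope$pass)
  # cubic: necessary sign condition only, slope is zero at the origin
  expect_true(crs$cubic$necessary_complete$pass)
  expect_false(crs$cubic$sufficient_slope$pass)
  expect_equal(crs$cubic$sufficient_slope$slope, 0, tolerance = 1e-6)
  # velocity-biased: recalibrates (sufficient), but only around its own
  # nonzero steady-state error, not around zero
  expect_false(crs$`velocity-biased`$necessary_complete$pass)
  expect_true(crs$`velocity-biased`$necessary_generalized$pass)
  expect_true(crs$`velocity-biased`$sufficient_slope$pass)
  # sign-flipped: fails everything and diverges
  expect_false(crs$`sign-flipped`$necessary_complete$pass)
  expect_false(crs$`sign-flipped`$sufficient_slope$pass)
  expect_gt(abs(crs$`sign-flipped`$k_tilde_final), 0.5)
  # report invariant: sufficient pass implies generalized-necessary pass
  for (cr in crs) {
    if (cr$sufficient_slope$pass) expect_true(cr$necessary_generalized$pass)
  }
  # serialization carries the verdicts
  js <- jsonlite::fromJSON(condition_report_json(crs$linear))
  expect_true(js$sufficient_slope)
  expect_equal(js$label, "linear")
})

test_that("probing the necessary condition rejects bad grids", {
  expect_error(check_necessary_condition(gain_rule_linear(0.02), c(0, 1)),
               "exclude 0")
  expect_error(check_sufficient_condition(gain_rule_linear(0.02), 0), "v0")
})

test_that("the linear rule recovers any visual gain within 2%", {
  beta <- beta_sinusoidal(0.66)
  rule <- gain_rule_linear(0.02)
  for (ks in c(0.5, 0.8, 1.0, 1.2, 1.5, 2.0)) {
    ed <- simulate_error_dynamics(0, ks - 1, v = 1, beta, rule,
                                  k_star = ks, duration = 400,
                                  dt = 0.01, record_dt = 400)
    expect_equal(ks - tail(ed$k_tilde, 1), ks, tolerance = 0.02,
                 label = sprintf("recovered gain at k* = %.1f", ks))
  }
})

test_that("slope-sign-preserving perturbations of the linear rule all converge", {
  beta <- beta_sinusoidal(0.66)
  set.seed(99)
  for (i in 1:6) {
    a <- runif(1, 0, 0.5); c3 <- runif(1, 0, 0.5); mu <- runif(1, 0.01, 0.05)
    g0 <- local({
      a <- a; c3 <- c3; mu <- mu
      function(k0, tt, v) mu * (tt * v * (1 + a * tt^2) + c3 * (tt * v)^3)
    })
    rule <- gain_rule(g0, label = sprintf("perturbed-%d", i))
    expect_true(check_sufficient_condition(rule, v0 = 1)$pass)
    ed <- simulate_error_dynamics(0, 0.5, v = 1, beta, rule,
                                  k_star = 1.5, duration = 500,
                                  dt = 0.01, record_dt = 500)
    expect_lt(abs(tail(ed$k_tilde, 1)), 0.02)
  }
})

test_that("the velocity-biased rule recalibrates partially to its own zero", {
  beta <- beta_sinusoidal(0.66)
  mu <- 0.02; eta <- 0.12; v <- 1
  rule <- gain_rule_velocity_biased(mu, eta)
  ed <- simulate_error_dynamics(0, 0.5, v, beta, rule, k_star = 1.5,
                                duration = 2000, dt = 0.01,
                                record_dt = 2000)
  tt_inf <- tail(ed$theta_tilde, 1)
  k0_inf <- tail(ed$k0, 1)
  # steady-state error sits at the rule's zero, magnitude eta * k0 * v
  expect_equal(tt_inf, -eta * k0_inf * v, tolerance = 0.05 * eta * v)
  expect_equal(abs(tt_inf) / (eta * v), k0_inf, tolerance = 0.05)
  # partial: gain error does not vanish
  expect_gt(abs(1.5 - k0_inf), 0.05)
})

test_that("gain trajectory under the linear rule equals its closed-form integral", {
  tr <- simulate_reduced(reduced_state(0, 0, 1), 1, 1.5,
                         beta_sinusoidal(0.66), gain_rule_linear(0.02),
                         duration = 60, dt = 0.005, record_dt = 0.05)
  # dk0/dt = mu * theta_tilde * v  =>  k0(T) = 1 + mu * int theta_tilde v dt
  integ <- cumsum(tr$theta_tilde * tr$v) * 0.05
  expect_equal(tail(tr$k0, 1), 1 + 0.02 * tail(integ, 1), tolerance = 2e-3)
})

test_that("mechanistic probes find the error code and collapse under shuffling", {
  tr <- simulate_reduced(reduced_state(0, 0, 1), 1, 1.5,
                         beta_sinusoidal(0.66), gain_rule_linear(0.02),
                         duration = 120, dt = 0.01, record_dt = 0.2)
  # synthesize rotation-ring proxies with the tuning the wiring imposes
  tr$mean_rccw <- 5 + 2 * tr$theta_tilde
  tr$mean_rcw <- 5 - 2 * tr$theta_tilde
  rep <- mechanistic_probe_report(tr, n_perm = 100, seed = 2)
  expect_gt(rep$probes$ccw_rate_vs_error$rho, 0.95)
  expect_lt(rep$probes$cw_rate_vs_error$rho, -0.95)
  # the slow variable (gain) tracks the integral of the error
  expect_gt(rep$probes$slow_var_vs_integral_error$rho, 0.95)
  # permutation control: chance correlations are near zero
  expect_lt(rep$probes$ccw_rate_vs_error$perm_q95_abs, 0.2)
})
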