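test_that("constant velocity profiles are constant", {
  vp <- make_velocity_profile("constant", duration = 60, mean_v = 0.7)
  expect_true(all(vp$v == 0.7))
  expect_true(all(diff(vp$times) > 0))
})

test_that("pause-resume pauses are exactly zero at the default times", {
  vp <- make_velocity_profile("pause_resume", duration = 1800, mean_v = 1)
  expect_true(all(vp$v[vp$times >= 300 & vp$times < 330] == 0))
  expect_true(all(vp$v[vp$times >= 1200 & vp$times < 1230] == 0))
  expect_true(all(vp$v[vp$times < 300] == 1))
  expect_true(all(vp$v[vp$times >= 330 & vp$times < 1200] == 1))
})

test_that("smoothed-random profiles are seed-reproducible and nonnegative", {
  a <- make_velocity_profile("smoothed_random", duration = 300, mean_v = 1,
                             seed = 5)
  b <- make_velocity_profile("smoothed_random", duration = 300, mean_v = 1,
                             seed = 5)
  c <- make_velocity_profile("smoothed_random", duration = 300, mean_v = 1,
                             seed = 6)
  expect_identical(a$v, b$v)
  expect_false(identical(a$v, c$v))
  expect_true(all(a$v >= 0))
})

test_that("velocity-neuron rate difference is affine in v on the linear range", {
  p <- base_params()
  v <- seq(-1.5, 1.5, by = 0.25)
  d <- vapply(v, function(vi) {
    u <- velocity_neuron_rates(vi, p)
    u$ccw - u$cw
  }, numeric(1))
  fit <- lm(d ~ v)
  expect_equal(unname(coef(fit)[2]), p$alpha_cw + p$alpha_ccw,
               tolerance = 1e-12)
  expect_equal(unname(coef(fit)[1]), p$u_ccw0 - p$u_cw0, tolerance = 1e-12)
  expect_lt(max(abs(residuals(fit))), 1e-12)
})

test_that("visual protocols validate their schedules", {
  expect_error(make_visual_protocol(1, list(c(10, 5))), "interval")
  expect_error(make_visual_protocol(1, list(c(0, 10), c(5, 15))),
               "overlap")
  pr <- make_visual_protocol(1.5, list(c(5, 10)))
  expect_true(ringrecal:::landmarks_on_at(pr, 4.9))
  expect_false(ringrecal:::landmarks_on_at(pr, 5))
  expect_false(ringrecal:::landmarks_on_at(pr, 9.99))
  expect_true(ringrecal:::landmarks_on_at(pr, 10))
  expect_equal(ringrecal:::k_star_at(pr, 3), 1.5)
})

test_that("a piecewise visual-gain schedule is honoured", {
  pr <- make_visual_protocol(cbind(c(0, 50), c(1, 1.5)))
  expect_equal(ringrecal:::k_star_at(pr, c(0, 49.9, 50, 80)),
               c(1, 1, 1.5, 1.5))
  expect_error(make_visual_protocol(cbind(c(50, 0), c(1, 1.5))), "sorted")
})

test_that("visual current vanishes throughout landmark-off intervals", {
  p <- base_params()
  proto <- make_visual_protocol(1, list(c(1, 2)))
  tr <- simulate_network(p, velocity = 0.5, visual = proto, duration = 3,
                         record_dt = 0.05)
  expect_true(all(!tr$landmarks_on[tr$t >= 1 & tr$t < 2]))
  expect_true(all(tr$landmarks_on[tr$t < 1]))
  # theta_star keeps integrating silently while off
  expect_gt(diff(range(tr$theta_star[tr$t >= 1 & tr$t < 2])), 0.3)
})
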