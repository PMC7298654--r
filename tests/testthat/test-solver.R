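test_that("no occlusion means no flow and no pressure", {
  cfg <- single_config(occlusion = 0)
  sol <- quick_solve(cfg, periods = 1)
  expect_equal(max(abs(sol$Q)), 0)
  expect_equal(max(abs(sol$p)), 0)
  cy <- cycle_average(sol)
  expect_equal(max(abs(cy$Q_peak)), 0)
  act <- pump_actuation(sol, 1)
  expect_equal(act$power_w, 0)
  expect_equal(act$displacement_m3_s, 0)
})

test_that("solution conserves mass and honors reservoir boundaries", {
  sol <- quick_solve(single_config(0.5))
  expect_lt(continuity_residual(sol), 1e-6)
  expect_equal(max(abs(sol$p[1, ])), 0)
  expect_equal(max(abs(sol$p[nrow(sol$p), ])), 0)
  # periodic steady state: mean Q is x-independent
  cy <- cycle_average(sol)
  expect_lt(diff(range(cy$Q_mean)) / abs(cy$Q_net), 0.01)
})

test_that("periodic wave train reproduces the closed-form mean flow", {
  # Independent oracle: for a traveling wave a(x - c t) with zero net
  # pressure rise per wavelength, the wave-frame flow q satisfies
  # int dp/dx = 0 => q = -pi c int(a^-2) / int(a^-4), and the time-mean
  # lab-frame flow is Q = q + pi c <a^2>.
  r0 <- 0.8e-3; phi <- 0.3; c0 <- 0.05; lam <- 0.1
  psi <- phi * (2 - phi)
  a_of <- function(s) r0 * sqrt(1 - (psi / 2) * (1 - cos(2 * pi * s / lam)))
  I2  <- stats::integrate(function(s) a_of(s)^2,  0, lam, rel.tol = 1e-10)$value
  Im2 <- stats::integrate(function(s) a_of(s)^-2, 0, lam, rel.tol = 1e-10)$value
  Im4 <- stats::integrate(function(s) a_of(s)^-4, 0, lam, rel.tol = 1e-10)$value
  Q_oracle <- pi * c0 * (I2 / lam - Im2 / Im4)
  cfg <- cascade_config(tube_spec(n_axial = 1001),
                        list(pump_unit(0.5, occlusion = phi,
                                       wave_speed_m_s = c0)),
                        waveform = "sine_train", wavelength_m = lam)
  sol <- solve_flow(cfg, periods = 1, discard = 0, steps_per_period = 64)
  expect_equal(cycle_average(sol)$Q_net, Q_oracle, tolerance = 0.02)
})

test_that("pressure is linear in viscosity at fixed kinematics", {
  cfg <- single_config(0.45)
  s1 <- quick_solve(cfg, newtonian_fluid(1), periods = 1)
  s2 <- quick_solve(cfg, newtonian_fluid(2), periods = 1)
  expect_equal(s2$p, 2 * s1$p, tolerance = 1e-12)
  expect_equal(s2$Q, s1$Q, tolerance = 1e-12)
})

test_that("power-law closure reduces to Newtonian at n = 1 and solves at n < 1", {
  cfg <- single_config(0.5)
  sN <- quick_solve(cfg, newtonian_fluid(0.7), periods = 1)
  s1 <- quick_solve(cfg, power_law_fluid(0.7, 1), periods = 1)
  expect_equal(s1$p, sN$p, tolerance = 1e-9)
  s05 <- quick_solve(cfg, power_law_fluid(1, 0.5), periods = 1)
  expect_lt(continuity_residual(s05), 1e-6)
  expect_lt(max(abs(s05$p[nrow(s05$p), ])) / max(s05$p), 1e-8)
})

test_that("identical dual units split the actuation symmetrically", {
  sol <- quick_solve(dual_config(0.3))
  a1 <- pump_actuation(sol, 1)
  a2 <- pump_actuation(sol, 2)
  expect_equal(a1$displacement_m3_s, a2$displacement_m3_s, tolerance = 0.02)
  expect_gt(a1$power_w, 0)
  expect_gt(a2$power_w, 0)
  expect_error(pump_actuation(sol, 3), "out of range")
})

test_that("cycle_average refuses less than one full period", {
  sol <- quick_solve(single_config(0.4), periods = 1)
  sol$t <- sol$t[1:10]
  sol$Q <- sol$Q[, 1:10]
  sol$p <- sol$p[, 1:10]
  expect_error(cycle_average(sol), "full retained period")
})

test_that("occlusion calibration converges, is a fixed point, and brackets", {
  cfg <- single_config(0.5)
  cal <- calibrate_occlusion(cfg, "peak_inplane_shear", 885,
                             steps_per_period = 48)
  rec <- attr(cal, "calibration")
  expect_equal(rec$achieved, 885, tolerance = 0.005)
  # re-measuring the calibrated config reproduces the anchor
  sol <- quick_solve(cal, periods = 1)
  eps <- peripump:::max_plane_metric(sol, 1, "epsilon")
  expect_equal(eps, 885, tolerance = 0.005)
  # feeding back the achieved value returns the config unchanged
  cal2 <- calibrate_occlusion(cal, "peak_inplane_shear", rec$achieved,
                              steps_per_period = 48)
  expect_equal(cal2$pumps[[1]]$occlusion, cal$pumps[[1]]$occlusion)
  expect_error(calibrate_occlusion(cfg, "total_actuation", 1e-3,
                                   steps_per_period = 48),
               "outside achievable bracket")
})
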