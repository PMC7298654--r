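test_that("passive region reconstructs steady Poiseuille flow", {
  sol <- quick_solve(single_config(0.5), periods = 1)
  t0 <- sol$t[5]
  fld <- reconstruct_velocity(sol, t0, window = c(0.3, 0.35), nx = 41, ny = 41)
  Q <- fld$Q[1]
  u_center <- fld$u[, fld$sigma == 0]
  expect_equal(u_center, rep(2 * Q / (pi * 0.8e-3^2), 41), tolerance = 1e-6)
  expect_lt(max(abs(fld$v)), 1e-12 * max(abs(fld$u)))
  # no slip at the walls
  expect_equal(max(abs(fld$u[, c(1, 41)])), 0)
})

test_that("reconstructed axial profile carries the local flow rate", {
  sol <- quick_solve(single_config(0.5), periods = 1)
  t0 <- peripump:::deepest_occlusion_time(sol$config, min(sol$t))
  fld <- reconstruct_velocity(sol, t0, window = c(0.07, 0.13),
                              nx = 121, ny = 81)
  pos <- fld$sigma >= 0
  for (i in seq(1, 121, by = 10)) {
    rho <- fld$sigma[pos] * fld$a[i]
    flux <- 2 * pi * pracma::trapz(rho, fld$u[i, pos] * rho)
    expect_equal(flux, fld$Q[i], tolerance = 0.005)
  }
})

test_that("radial velocity matches the wall motion at the moving boundary", {
  sol <- quick_solve(dual_config(0.35), periods = 1)
  t0 <- min(sol$t) + 0.3 * sol$period
  fld <- reconstruct_velocity(sol, t0, window = c(0.08, 0.12), nx = 61, ny = 41)
  adot <- occlusion_rate(sol$config, fld$x, t0)
  expect_equal(fld$v[, 41], adot, tolerance = 1e-8)
  expect_equal(fld$v[, 1], -adot, tolerance = 1e-8)
})

test_that("reconstruction rejects out-of-domain requests", {
  sol <- quick_solve(single_config(0.4), periods = 1)
  expect_error(reconstruct_velocity(sol, max(sol$t) + 1), "time span")
  expect_error(reconstruct_velocity(sol, sol$t[2], window = c(0.5, 1.5)),
               "window")
})

test_that("gradients vanish for rigid translation", {
  fld <- make_fixture("rigid", list(U = 0.02))
  g <- compute_gradients(fld)
  for (nm in c("du_dx", "du_dy", "du_dz", "dv_dx", "dv_dy", "dv_dz",
               "dw_dx", "dw_dy", "dw_dz"))
    expect_equal(max(abs(g[[nm]])), 0)
})

test_that("Poiseuille wall gradient matches the analytic parabola slope", {
  Q <- 2e-8; a0 <- 0.8e-3
  fld <- make_fixture("poiseuille", list(Q = Q, a = a0))
  g <- compute_gradients(fld)
  wall <- 4 * Q / (pi * a0^3)
  ny <- length(fld$sigma)
  expect_equal(abs(g$du_dy[, ny]), rep(wall, length(fld$x)), tolerance = 1e-9)
  expect_equal(abs(g$du_dy[, 1]), rep(wall, length(fld$x)), tolerance = 1e-9)
})

test_that("substitution convention stores z-entries as their y analogues", {
  sol <- quick_solve(single_config(0.5), periods = 1)
  t0 <- peripump:::deepest_occlusion_time(sol$config, min(sol$t))
  fld <- reconstruct_velocity(sol, t0, window = c(0.08, 0.12), nx = 41, ny = 31)
  g <- compute_gradients(fld, "paper_substitution")
  expect_identical(g$du_dz, g$du_dy)
  expect_identical(g$dw_dx, g$dv_dx)
  expect_identical(g$dw_dy, g$dv_dy)
  expect_identical(g$dw_dz, g$dv_dy)
  expect_identical(g$dv_dz, g$dv_dy)
  gt <- compute_gradients(fld, "true_axisymmetric")
  expect_equal(max(abs(gt$du_dz)), 0)
  expect_error(compute_gradients(make_fixture("rigid", nx = 2, ny = 2)),
               "too coarse")
})

test_that("reconstructed field is divergence-free and has the right parity", {
  sol <- quick_solve(single_config(0.5), periods = 1)
  t0 <- peripump:::deepest_occlusion_time(sol$config, min(sol$t))
  fld <- reconstruct_velocity(sol, t0, window = c(0.07, 0.13),
                              nx = 161, ny = 81)
  expect_lt(peripump:::divergence_residual(fld), 1e-3)
  # u even, v odd in the signed radial coordinate
  ny <- length(fld$sigma)
  expect_equal(fld$u, fld$u[, ny:1], tolerance = 1e-12)
  expect_equal(fld$v, -fld$v[, ny:1], tolerance = 1e-12)
})
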