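# Metric oracles on analytic fixtures, plane extraction and histograms.

test_that("metrics match closed forms on analytic fixtures", {
  Q <- 1.5e-8; a0 <- 0.8e-3
  po <- make_fixture("poiseuille", list(Q = Q, a = a0))
  g <- compute_gradients(po)
  eps <- inplane_shear(g); eta <- extensional_strain(g)
  gam <- total_shear_eq1(g)
  orc <- attr(po, "oracle")
  expect_equal(max(abs(eps$values)), orc$epsilon_wall, tolerance = 0.005)
  expect_lt(max(abs(eta$values)), 0.005 * orc$epsilon_wall)
  # under the substitution convention only (dv/dx + du/dy)^2 and
  # (du/dz + dw/dx)^2 survive for a parabola: |gamma| = sqrt(2) |du/dy|
  expect_equal(max(gam$values), orc$gamma_wall, tolerance = 0.005)
  # the true axisymmetric tensor has no duplicated shear term: |gamma| = |du/dy|
  gam_true <- total_shear_eq1(compute_gradients(po, "true_axisymmetric"))
  expect_equal(max(gam$values) / max(gam_true$values), sqrt(2),
               tolerance = 1e-6)

  ri <- make_fixture("rigid", list(U = 0.05))
  gri <- compute_gradients(ri)
  expect_equal(max(abs(inplane_shear(gri)$values)), 0)
  expect_equal(max(abs(total_shear_eq1(gri)$values)), 0)

  pe <- make_fixture("pure_extension", list(alpha = 3))
  gpe <- compute_gradients(pe)
  orc <- attr(pe, "oracle")
  expect_lt(max(abs(inplane_shear(gpe)$values)), 1e-9)
  expect_equal(max(extensional_strain(gpe)$values), orc$eta, tolerance = 0.005)
  expect_equal(max(total_shear_eq1(gpe)$values), orc$gamma_wall,
               tolerance = 0.005)
})

test_that("yz cross-section equals the meridional profile by axisymmetry", {
  po <- make_fixture("poiseuille", list(Q = 1e-8, a = 0.8e-3))
  gam <- total_shear_eq1(compute_gradients(po))
  yz <- extract_plane(gam, "yz_cross_section", x0 = 0.01)
  # radially increasing from 0 at the axis to the wall maximum
  expect_equal(yz$values[1], 0, tolerance = 1e-9 * max(yz$values))
  expect_true(all(diff(yz$values) >= -1e-9 * max(yz$values)))
  i <- which.min(abs(gam$x - yz$x0))
  pos <- gam$sigma >= 0
  expect_equal(yz$values, gam$values[i, pos])
  expect_error(extract_plane(gam, "yz_cross_section", x0 = 5), "outside")
  expect_error(extract_plane(gam, "yz_cross_section"), "x0")
})

test_that("histograms are normalized, binned and weighted correctly", {
  po <- make_fixture("poiseuille", list(Q = 1e-8, a = 0.8e-3))
  gam <- total_shear_eq1(compute_gradients(po))
  xy <- extract_plane(gam, "xy_meridional")
  h <- shear_histogram(xy, bin_width = 100)
  expect_equal(sum(h$frequency), 1, tolerance = 1e-9)
  expect_true(all(diff(h$breaks) > 0))
  expect_error(shear_histogram(xy, bin_width = -5), "positive")
  # uniform field: all mass in the first bin
  uni <- xy; uni$values[] <- 50
  h1 <- shear_histogram(uni, bin_width = 100)
  expect_equal(h1$frequency[1], 1)
  # annulus weighting: yz histogram of Poiseuille |gamma| = g_wall * rho/a
  # has CDF (rho/a)^2, so the mass below half the maximum is 1/4
  fine <- make_fixture("poiseuille", list(Q = 1e-8, a = 0.8e-3), ny = 201)
  gfine <- total_shear_eq1(compute_gradients(fine))
  yz <- extract_plane(gfine, "yz_cross_section", x0 = 0.01)
  hy <- shear_histogram(yz, bin_width = max(yz$values) / 2 * 1.0000001)
  expect_equal(hy$frequency[1], 0.25, tolerance = 0.02)
})

test_that("self-comparison yields unit ratios and zero fold reductions", {
  sol <- quick_solve(single_config(0.5), periods = 1)
  rep1 <- shear_report(sol)
  cmp <- compare_conditions(list(a = rep1, b = rep1))
  expect_true(all(abs(cmp$table$ratio_to_first - 1) < 1e-12))
  expect_true(all(abs(cmp$table$fold_reduction) < 1e-12))
  expect_error(compare_conditions(list(rep1)), "2")
})

test_that("extensional strain is a small fraction of in-plane shear", {
  # scale audit: eta/eps is of the order of the radius over the bump width
  sol <- quick_solve(single_config(0.5), periods = 1)
  rep1 <- shear_report(sol)
  eps <- rep1$pumps[[1]]$xy$epsilon$value
  eta <- rep1$pumps[[1]]$xy$eta$value
  expect_lt(eta, 0.1 * eps)
  expect_gt(eta, 0)
})

test_that("reported maxima store the grid point where they occur", {
  sol <- quick_solve(single_config(0.5), periods = 1)
  rep1 <- shear_report(sol)
  m <- rep1$pumps[[1]]$xy$gamma
  expect_true(m$x >= rep1$pumps[[1]]$window[1] &&
                m$x <= rep1$pumps[[1]]$window[2])
  expect_true(abs(m$sigma) <= 1)
})
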