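test_that("presets carry the reference geometry", {
  pr <- cascade_presets()
  expect_named(pr, c("single_0.1", "dual_0.1_0.5", "sweep_0.2", "sweep_0.3",
                     "sweep_0.4", "sweep_0.5"))
  for (p in pr) {
    expect_equal(p$config$tube$length_m, 1.0)
    expect_equal(p$config$tube$inner_radius_m, 0.8e-3)
    for (pu in p$config$pumps)
      expect_equal(pu$deformation_length_m, 0.04)
  }
  centers <- function(p) vapply(p$config$pumps, function(u) u$center_m,
                                numeric(1))
  expect_equal(centers(pr$single_0.1), 0.1)
  expect_equal(centers(pr$dual_0.1_0.5), c(0.1, 0.5))
  expect_equal(vapply(pr[3:6], function(p) centers(p)[2], numeric(1)),
               c(0.2, 0.3, 0.4, 0.5), ignore_attr = TRUE)
  expect_true(all(vapply(pr[3:6], function(p) centers(p)[1], numeric(1)) ==
                    0.1))
  expect_error(realize_scenario("nope"), "unknown preset")
})

test_that("scenario files round-trip through the YAML schema", {
  cfg <- dual_config(0.3)
  fl <- power_law_fluid(2, 0.6)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path, fluid = fl,
               solver = list(periods = 2, discard = 3, steps_per_period = 48))
  got <- load_config(path)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_config(got$config, path2, fluid = got$fluid, solver = got$solver)
  expect_identical(readLines(path), readLines(path2))
  expect_equal(got$config$pumps[[2]]$center_m, 0.5)
  expect_s3_class(got$fluid, "power_law_fluid")
  expect_equal(got$solver$steps_per_period, 48)
})

test_that("missing blocks take defaults and unknown keys are named", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("pumps:\n- center_m: 0.1\n", path)
  got <- load_config(path)
  expect_equal(got$config$tube$length_m, 1.0)
  expect_equal(got$config$tube$inner_radius_m, 0.8e-3)
  expect_s3_class(got$fluid, "newtonian_fluid")
  writeLines("tube:\n  radius: 1\n", path)
  expect_error(load_config(path), "radius")
  writeLines("pumps:\n- center_m: 0.1\n- center_m: 0.12\n", path)
  expect_error(load_config(path), "overlap")
  expect_error(load_config("does-not-exist.yaml"), "no such file")
})

test_that("report directories are deterministic with valid checksums", {
  sol <- quick_solve(single_config(0.5), periods = 1)
  rep1 <- shear_report(sol, nx = 81, ny = 41)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_report(rep1, d1)
  m2 <- write_report(rep1, d2)
  expect_equal(m1$md5, m2$md5)
  expect_true(all(c("shear_summary.json", "pressure_profile.csv",
                    "flow_profile.csv", "histogram_xy_pump1.csv") %in%
                    m1$file))
  # checksums match the files on disk
  expect_equal(unname(tools::md5sum(file.path(d1, m1$file))), m1$md5)
  gel <- gelling_fluid(plateau_mult = 50, onset_s = 100, rise_s = 20)
  cr <- simulate_transit(single_config(0.5), gel, t_end = 300, n_axial = 101)
  m3 <- write_report(cr, withr::local_tempdir())
  expect_true("clog_report.json" %in% m3$file)
})

test_that("fixture generator attaches its closed-form metrics", {
  ri <- make_fixture("rigid")
  expect_equal(unlist(attr(ri, "oracle")), c(epsilon_wall = 0, eta = 0,
                                             gamma_wall = 0))
  po <- make_fixture("poiseuille", list(Q = 1e-8, a = 0.8e-3))
  expect_equal(attr(po, "oracle")$epsilon_wall, 4e-8 / (pi * 0.8e-3^3))
  expect_error(make_fixture("vortex"), "arg")
})
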