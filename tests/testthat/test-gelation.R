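test_that("age transport follows the characteristics", {
  n <- 101; L <- 1; dx <- L / (n - 1)
  # stagnant fluid ages in place (inlet pinned to zero)
  age <- numeric(n)
  for (k in 1:50) age <- advect_age(age, 0, dx, dt = 1)
  expect_equal(age[-1], rep(50, n - 1))
  expect_equal(age[1], 0)
  # steady uniform flow: tau(x) = x / U, outlet age = transit time L / U
  U <- 0.01
  dt <- 0.5 * dx / U
  age <- numeric(n)
  for (k in 1:2000) age <- advect_age(age, U, dx, dt)
  x <- seq(0, L, length.out = n)
  expect_equal(age, x / U, tolerance = 0.02)
  expect_equal(age[n], L / U, tolerance = 0.02)
  expect_error(advect_age(age, U, dx, dt = 10 * dx / U), "CFL")
})

test_that("non-gelling fluid flows indefinitely and warns", {
  cfg <- single_config(0.5)
  expect_warning(
    rep0 <- simulate_transit(cfg, gelling_fluid(plateau_mult = 1),
                             t_end = 600),
    NA)                       # plateau 1 gels nowhere but is a gelling model
  expect_true(is.na(rep0$clog_time_s))
  expect_equal(diff(range(rep0$Q_m3_s)) / rep0$Q_init, 0, tolerance = 1e-9)
  expect_warning(simulate_transit(cfg, newtonian_fluid(), t_end = 10),
                 "does not gel")
})

test_that("strong fast gelation clogs in finite time", {
  cfg <- single_config(0.5)
  gel <- gelling_fluid(plateau_mult = 1e4, onset_s = 60, rise_s = 10)
  rep1 <- simulate_transit(cfg, gel, t_end = 1200)
  expect_false(is.na(rep1$clog_time_s))
  expect_lt(rep1$clog_time_s, 300)
})

test_that("pump demands balance the series pressure drops", {
  cfg <- dual_config(0.25)
  gel <- gelling_fluid(plateau_mult = 100, onset_s = 300, rise_s = 60)
  rep1 <- simulate_transit(cfg, gel, t_end = 1500, n_axial = 101)
  # after throttling, total demand equals total capacity
  k <- length(rep1$time_s)
  expect_equal(sum(rep1$demand_pa[k, ]), sum(rep1$capacities_pa),
               tolerance = 1e-9)
  # before gelation bites, demand is far below capacity
  expect_lt(sum(rep1$demand_pa[1, ]), sum(rep1$capacities_pa))
})

test_that("clog time is monotone in gel strength and onset", {
  cfg <- single_config(0.5)
  base <- list(onset_s = 200, rise_s = 40)
  ct <- function(m, on) {
    gel <- gelling_fluid(plateau_mult = m, onset_s = on, rise_s = 40)
    t_clog <- simulate_transit(cfg, gel, t_end = 2500,
                               n_axial = 101)$clog_time_s
    if (is.na(t_clog)) Inf else t_clog   # no clog counts as "latest"
  }
  ms <- c(30, 100, 1000)
  t_m <- vapply(ms, ct, numeric(1), on = 200)
  expect_true(all(diff(t_m) <= 0))
  ons <- c(100, 300, 600)
  t_o <- vapply(ons, function(o) ct(100, o), numeric(1))
  expect_true(all(diff(t_o) >= 0))
})

test_that("equal total capacity: single clogs no later than the cascade", {
  # sweep over gel strength and onset; capacities matched in total
  single <- single_config(0.5348)
  dual <- dual_config(0.2204)
  ref <- simulate_transit(single,
                          gelling_fluid(plateau_mult = 100, onset_s = 300,
                                        rise_s = 60),
                          t_end = 10, n_axial = 101)
  cap <- sum(ref$capacities_pa)
  qs <- ref$q_set
  for (m in c(50, 500)) for (on in c(200, 500)) {
    gel <- gelling_fluid(plateau_mult = m, onset_s = on, rise_s = 60)
    ts <- simulate_transit(single, gel, capacities_pa = cap, q_set = qs,
                           t_end = 2000, n_axial = 101)$clog_time_s
    td <- simulate_transit(dual, gel, capacities_pa = cap / 2, q_set = qs,
                           t_end = 2000, n_axial = 101)$clog_time_s
    if (is.na(ts)) expect_true(is.na(td))
    else expect_true(is.na(td) || ts <= td + 1e-9)
  }
})

test_that("configuration comparison reports identical rows for identical runs", {
  cfg <- single_config(0.5)
  gel <- gelling_fluid(plateau_mult = 200, onset_s = 150, rise_s = 30)
  r1 <- simulate_transit(cfg, gel, t_end = 800, n_axial = 101)
  r2 <- simulate_transit(cfg, gel, t_end = 800, n_axial = 101)
  tab <- compare_configurations(list(a = r1, b = r2))
  expect_equal(tab$clog_time_s[1], tab$clog_time_s[2])
  expect_equal(tab$sustained_fraction[1], tab$sustained_fraction[2])
  r3 <- r2; r3$fluid <- gelling_fluid(plateau_mult = 5)
  expect_error(compare_configurations(list(a = r1, b = r3)),
               "different fluids")
})
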