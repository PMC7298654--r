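# Lumped residence-time gelation and clogging model.
#
# The gelation timescale (minutes) is separated from the peristaltic cycle
# (sub-second) by more than three orders of magnitude, so the transit model
# is quasi-static: the fast cycle supplies a target mean flow rate and a
# per-pump pressure capacity, while on the slow timescale the material age
# field advects downstream, raises the local apparent viscosity, and with it
# the series hydraulic resistance 8 mu dx / (pi a^4) that the pumps must
# overcome. Flow collapses ("clogs") when the summed pressure demand exceeds
# the summed pump capacity.

#' Advect a material-age field
#'
#' One explicit upwind step of the residence-time transport equation
#' `dtau/dt + u dtau/dx = 1` with inlet age pinned to zero: ages are carried
#' downstream and every parcel grows older by `dt`.
#'
#' @param age Age field tau(x), seconds, on a uniform axial grid.
#' @param u_mean Mean axial velocity, m/s: scalar or per-node (>= 0).
#' @param dx Grid spacing, meters.
#' @param dt Time step, seconds; must respect the CFL condition
#'   `dt <= dx / max(u)`.
#' @return The advanced age field.
#' @export
advect_age <- function(age, u_mean, dx, dt) {
  if (any(age < 0)) stop("ages must be >= 0", call. = FALSE)
  u <- rep_len(u_mean, length(age))
  if (any(u < 0)) stop("reverse mean flow not supported by the upwind step",
                       call. = FALSE)
  if (dt > dx / max(max(u), .Machine$double.eps))
    stop("CFL violation: dt > dx / max(u)", call. = FALSE)
  n <- length(age)
  upwind <- c(0, age[-n])      # inlet ghost value 0
  out <- age - dt * u / dx * (age - upwind) + dt
  out[1] <- 0
  out
}

# Pump segment boundaries: pump i is responsible for the tube from its own
# center to the next pump's center (the first pump also covers the inlet
# run, the last pump the run to the outlet).
pump_segments <- function(config) {
  ctr <- vapply(config$pumps, function(p) p$center_m, numeric(1))
  lo <- c(0, ctr[-1])
  hi <- c(ctr[-1], config$tube$length_m)
  cbind(lo = lo, hi = hi)
}

#' Simulate the transit of a gelling fluid
#'
#' Quasi-static clogging model: starting from fresh fluid everywhere, the
#' age field is advected with the mean flow, the age- and shear-dependent
#' apparent viscosity sets the per-segment hydraulic resistance, and the
#' flow rate is throttled to what the summed pump pressure capacity can
#' drive: `Q(t) = min(Q_set, sum(capacity) / R_total(t))`. Intermediate node
#' pressures are unconstrained (the units can hold suction), so capacities
#' in series add. A clog is declared at the first instant `Q` falls below
#' 10 % of its initial value.
#'
#' @param config A [cascade_config()].
#' @param fluid A [gelling_fluid()] (a non-gelling model yields a constant
#'   flow and a warning).
#' @param capacities_pa Per-pump pressure capacities, pascals; recycled over
#'   pumps. Default: taken from each unit's `capacity_pa`, else derived as
#'   the maximum cycle pressure of a reference lubrication run, split
#'   equally over the pumps.
#' @param q_set Target mean flow rate, m^3/s. Default: the cycle-mean flow
#'   of a reference lubrication run of `config`.
#' @param t_end Simulated transit time, seconds.
#' @param n_axial Axial grid nodes for the age field.
#' @param dt Slow time step, seconds; default obeys CFL with margin.
#' @return A `clog_report`: time series of flow and per-segment pressure
#'   demand, per-pump load fractions, clog time (or `NA`), and the
#'   configuration echo.
#' @export
simulate_transit <- function(config, fluid, capacities_pa = NULL,
                             q_set = NULL, t_end = 3600, n_axial = 201L,
                             dt = NULL) {
  stopifnot(inherits(config, "cascade_config"), length(config$pumps) > 0)
  gelling <- inherits(fluid, "gelling_fluid")
  if (!gelling)
    warning("fluid does not gel: flow will not clog", call. = FALSE)
  L <- config$tube$length_m
  r0 <- config$tube$inner_radius_m
  x <- seq(0, L, length.out = n_axial)
  dx <- x[2] - x[1]
  need_ref <- is.null(q_set) ||
    (is.null(capacities_pa) &&
       any(vapply(config$pumps, function(p) is.null(p$capacity_pa),
                  logical(1))))
  if (need_ref) {
    base <- if (gelling) fluid$base else fluid
    ref <- solve_flow(config, base, periods = 1, discard = 3)
    if (is.null(q_set)) q_set <- abs(cycle_average(ref)$Q_net)
    if (is.null(capacities_pa)) {
      given <- vapply(config$pumps, function(p)
        if (is.null(p$capacity_pa)) NA_real_ else p$capacity_pa, numeric(1))
      capacities_pa <- ifelse(is.na(given),
                              max(ref$p) / length(config$pumps), given)
    }
  } else if (is.null(capacities_pa)) {
    capacities_pa <- vapply(config$pumps, function(p) p$capacity_pa,
                            numeric(1))
  }
  capacities_pa <- rep_len(capacities_pa, length(config$pumps))
  if (q_set <= 0) stop("q_set must be positive", call. = FALSE)
  u0 <- q_set / (pi * r0^2)
  if (is.null(dt)) dt <- 0.5 * dx / u0
  seg <- pump_segments(config)
  nseg <- nrow(seg)
  seg_idx <- lapply(seq_len(nseg), function(i)
    which(x >= seg[i, "lo"] & x <= seg[i, "hi"]))
  nt <- max(2L, ceiling(t_end / dt))
  age <- numeric(n_axial)
  times <- Q_ts <- numeric(nt)
  demand_ts <- matrix(0, nt, nseg)
  Q <- q_set
  Q_init <- NA_real_
  clog_time <- NA_real_
  for (k in seq_len(nt)) {
    tk <- k * dt
    gw <- 4 * Q / (pi * r0^3)               # wall shear of the mean flow
    mu <- if (gelling) apparent_viscosity(fluid, gw, age)
          else rep_len(apparent_viscosity(fluid, gw), n_axial)
    rpl <- 8 * mu / (pi * r0^4)             # resistance per unit length
    R_seg <- vapply(seg_idx, function(ii)
      pracma::trapz(x[ii], rpl[ii]), numeric(1))
    R_tot <- sum(R_seg)
    Q <- min(q_set, sum(capacities_pa) / R_tot)
    if (k == 1L) Q_init <- Q
    if (is.na(clog_time) && Q < 0.1 * Q_init) clog_time <- tk
    times[k] <- tk
    Q_ts[k] <- Q
    demand_ts[k, ] <- Q * R_seg
    age <- advect_age(age, Q / (pi * r0^2), dx, dt)
  }
  load_frac <- demand_ts[nt, ] / capacities_pa
  structure(list(time_s = times, Q_m3_s = Q_ts, demand_pa = demand_ts,
                 capacities_pa = capacities_pa, segments = seg,
                 load_fraction = load_frac, clog_time_s = clog_time,
                 Q_init = Q_init, q_set = q_set,
                 sustained_fraction = mean(Q_ts >= 0.1 * Q_init),
                 config = config, fluid = fluid),
            class = "clog_report")
}

#' Compare clogging behavior across configurations
#'
#' Tabulates clog times, sustained-flow fractions and per-pump load
#' fractions of two or more transit reports for the same fluid.
#'
#' @param reports Named list of `clog_report`s (>= 2).
#' @return A data frame, one row per report.
#' @export
compare_configurations <- function(reports) {
  stopifnot(length(reports) >= 2,
            all(vapply(reports, inherits, logical(1), "clog_report")))
  f1 <- reports[[1]]$fluid
  same <- vapply(reports, function(r) identical(r$fluid, f1), logical(1))
  if (!all(same)) stop("reports use different fluids", call. = FALSE)
  if (is.null(names(reports)))
    names(reports) <- paste0("config_", seq_along(reports))
  data.frame(
    scenario = names(reports),
    n_pumps = vapply(reports, function(r) length(r$config$pumps), integer(1)),
    total_capacity_pa = vapply(reports, function(r) sum(r$capacities_pa),
                               numeric(1)),
    clog_time_s = vapply(reports, function(r) r$clog_time_s, numeric(1)),
    sustained_fraction = vapply(reports, function(r) r$sustained_fraction,
                                numeric(1)),
    peak_load_fraction = vapply(reports, function(r) max(r$load_fraction),
                                numeric(1)),
    row.names = NULL)
}

#' @export
print.clog_report <- function(x, ...) {
  cat(sprintf("<clog_report> %d pump(s), total capacity %.4g Pa\n",
              length(x$config$pumps), sum(x$capacities_pa)))
  cat(sprintf("  initial Q %.4g m^3/s; final Q %.4g m^3/s\n",
              x$Q_init, x$Q_m3_s[length(x$Q_m3_s)]))
  if (is.na(x$clog_time_s)) cat("  no clog within the simulated window\n")
  else cat(sprintf("  clogged at t = %.4g s\n", x$clog_time_s))
  invisible(x)
}

#' @export
plot.clog_report <- function(x, ...) {
  graphics::plot(x$time_s, x$Q_m3_s, type = "l", xlab = "time (s)",
                 ylab = "mean flow rate (m^3/s)", ...)
  if (!is.na(x$clog_time_s))
    graphics::abline(v = x$clog_time_s, lty = 2)
  invisible(x)
}
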