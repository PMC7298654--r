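#' Tube geometry specification
#'
#' Defines the flexible tube through which the fluid is pumped: its length,
#' undeformed inner radius, and the default axial grid resolution used by the
#' lubrication solver. Defaults correspond to a 1 m silicone tube of inner
#' diameter 1.6 mm.
#'
#' @param length_m Tube length in meters (> 0).
#' @param inner_radius_m Undeformed inner radius in meters (> 0).
#' @param n_axial Number of axial grid nodes used by default when solving.
#'   Must resolve the pump deformation length (at least 20 nodes per
#'   deformation length is enforced at solve time).
#' @return An object of class `tube_spec`.
#' @export
#' @examples
#' tube_spec()
tube_spec <- function(length_m = 1.0, inner_radius_m = 0.8e-3, n_axial = 801L) {
  stopifnot(is.numeric(length_m), length(length_m) == 1L, length_m > 0,
            is.numeric(inner_radius_m), length(inner_radius_m) == 1L,
            inner_radius_m > 0, n_axial >= 3)
  structure(list(length_m = length_m,
                 inner_radius_m = inner_radius_m,
                 n_axial = as.integer(n_axial)),
            class = "tube_spec")
}

#' Peristaltic pump unit
#'
#' One pumping unit (one channel of a multi-channel roller pump) acting on a
#' "shoe" segment of the tube. A roller traverses the shoe and locally
#' occludes the tube; `occlusion` is the fractional radius reduction at the
#' deepest point of the squeeze.
#'
#' @param center_m Axial position of the shoe center, meters from the inlet.
#' @param deformation_length_m Length of the deformed (shoe) segment, meters.
#'   Default 0.04 (4 cm).
#' @param occlusion Fractional occlusion `phi` in `[0, 0.95)`: the minimum
#'   inner radius during the squeeze is `(1 - phi) * r0`.
#' @param wave_speed_m_s Roller travel speed along the tube, m/s. The
#'   default 0.025 places the shear-anchored reference scenario's
#'   peak-to-steady flow ratio inside the expected one-to-two orders of
#'   magnitude band.
#' @param phase Phase offset of the roller cycle, radians.
#' @param n_rollers Number of rollers engaged on the shoe, evenly staggered
#'   in phase. Default 2: with two staggered rollers the shoe's total
#'   occluded volume is constant in time (as in a physical roller pump that
#'   always keeps one roller engaged), so the unit pumps without pulsating
#'   suction/discharge through the reservoirs. Set 1 for a single roller
#'   that engages and disengages each cycle.
#' @param capacity_pa Pressure capacity of the unit, pascals; used by the
#'   gelation/clogging model. `NULL` means "derive from the flow solution".
#' @return An object of class `pump_unit`.
#' @export
#' @examples
#' pump_unit(center_m = 0.1)
pump_unit <- function(center_m, deformation_length_m = 0.04, occlusion = 0.5,
                      wave_speed_m_s = 0.025, phase = 0, n_rollers = 2L,
                      capacity_pa = NULL) {
  stopifnot(is.numeric(center_m), length(center_m) == 1L,
            deformation_length_m > 0, wave_speed_m_s > 0,
            n_rollers >= 1)
  if (occlusion < 0 || occlusion >= 0.95)
    stop("`occlusion` must lie in [0, 0.95): near-total occlusion makes the ",
         "lubrication resistance a^-4 unbounded", call. = FALSE)
  structure(list(center_m = center_m,
                 deformation_length_m = deformation_length_m,
                 occlusion = occlusion,
                 wave_speed_m_s = wave_speed_m_s,
                 phase = phase,
                 n_rollers = as.integer(n_rollers),
                 capacity_pa = capacity_pa),
            class = "pump_unit")
}

#' Full pumping scenario configuration
#'
#' A tube plus an ordered list of pump units and a waveform tag. Pump
#' footprints (`center +/- deformation_length/2`) must lie inside the tube and
#' be pairwise disjoint; pumps are sorted by center position.
#'
#' @param tube A [tube_spec()].
#' @param pumps A list of [pump_unit()] objects (a bare `pump_unit` is
#'   accepted and wrapped).
#' @param waveform Occlusion waveform: `"bump"` (default) is a traveling
#'   raised-cosine roller squeeze confined to each shoe; `"sine_train"` is an
#'   infinite sinusoidal wave train over the whole tube (used for validating
#'   the solver against the classical closed-form mean flow).
#' @param wavelength_m Wavelength of the `"sine_train"` waveform, meters.
#'   Ignored for `"bump"`.
#' @return An object of class `cascade_config`.
#' @export
#' @examples
#' cfg <- cascade_config(tube_spec(), list(pump_unit(0.1)))
#' cfg
cascade_config <- function(tube = tube_spec(), pumps = list(),
                           waveform = c("bump", "sine_train"),
                           wavelength_m = NULL) {
  waveform <- match.arg(waveform)
  stopifnot(inherits(tube, "tube_spec"))
  if (inherits(pumps, "pump_unit")) pumps <- list(pumps)
  stopifnot(all(vapply(pumps, inherits, logical(1), "pump_unit")))
  if (length(pumps) > 0) {
    ord <- order(vapply(pumps, function(p) p$center_m, numeric(1)))
    pumps <- pumps[ord]
    lo <- vapply(pumps, function(p) p$center_m - p$deformation_length_m / 2,
                 numeric(1))
    hi <- vapply(pumps, function(p) p$center_m + p$deformation_length_m / 2,
                 numeric(1))
    if (waveform == "bump") {
      if (any(lo < 0) || any(hi > tube$length_m))
        stop("pump footprint extends outside the tube [0, L]", call. = FALSE)
      if (length(pumps) > 1 && any(lo[-1] < hi[-length(hi)]))
        stop("pump footprints overlap", call. = FALSE)
    }
  }
  if (waveform == "sine_train") {
    if (length(pumps) != 1L)
      stop("`sine_train` waveform takes exactly one pump unit (its occlusion ",
           "and wave speed parameterize the train)", call. = FALSE)
    if (is.null(wavelength_m) || wavelength_m <= 0)
      stop("`sine_train` waveform requires a positive `wavelength_m`",
           call. = FALSE)
  }
  structure(list(tube = tube, pumps = pumps, waveform = waveform,
                 wavelength_m = wavelength_m),
            class = "cascade_config")
}

#' @export
print.cascade_config <- function(x, ...) {
  cat(sprintf("<cascade_config> tube L = %g m, r0 = %g mm, waveform = %s\n",
              x$tube$length_m, 1e3 * x$tube$inner_radius_m, x$waveform))
  for (p in x$pumps)
    cat(sprintf("  pump at %.3f m: L_d = %g cm, occlusion = %.4f, c = %g m/s\n",
                p$center_m, 100 * p$deformation_length_m, p$occlusion,
                p$wave_speed_m_s))
  invisible(x)
}

#' Roller cycle period of a pump unit
#'
#' The occlusion bump (width half the deformation length) sweeps the interior
#' of the shoe at the roller speed and restarts each cycle, so the period is
#' `(L_d - w) / c = L_d / (2 c)`.
#'
#' @param pump A [pump_unit()].
#' @return Period in seconds.
#' @export
pump_period <- function(pump) {
  w <- pump$deformation_length_m / 2
  (pump$deformation_length_m - w) / pump$wave_speed_m_s
}

# Common period of all pumps in a config (solver requires equal periods so
# that the flow is periodic); sine_train period is wavelength / c.
config_period <- function(config) {
  if (config$waveform == "sine_train")
    return(config$wavelength_m / config$pumps[[1]]$wave_speed_m_s)
  if (length(config$pumps) == 0L) return(NA_real_)
  per <- vapply(config$pumps, pump_period, numeric(1))
  if (diff(range(per)) > 1e-12 * per[1])
    stop("pump units have unequal cycle periods; a common period is required ",
         "for periodic analysis", call. = FALSE)
  per[1]
}

# Raised-cosine bump profile and derivative, compactly supported on
# |zeta| <= w/2. Vectorized; C^1 at the support edge.
bump_profile <- function(zeta, w) {
  inside <- abs(zeta) <= w / 2
  out <- numeric(length(zeta))
  out[inside] <- cos(pi * zeta[inside] / w)^2
  out
}

bump_profile_d <- function(zeta, w) {
  inside <- abs(zeta) <= w / 2
  out <- numeric(length(zeta))
  out[inside] <- -(pi / w) * sin(2 * pi * zeta[inside] / w)
  out
}

bump_profile_dd <- function(zeta, w) {
  inside <- abs(zeta) <= w / 2
  out <- numeric(length(zeta))
  out[inside] <- -(2 * pi^2 / w^2) * cos(2 * pi * zeta[inside] / w)
  out
}

# Area-occlusion fraction for one pump: the traveling squeeze is applied to
# the cross-sectional area, pi a^2 = pi r0^2 (1 - psi E B), with amplitude
# psi = phi (2 - phi) chosen so that the minimum radius at the deepest
# instant is exactly (1 - phi) r0. Parameterizing the area (rather than the
# radius) makes the wall displacement source d(pi a^2)/dt exactly linear in
# the occlusion amplitude, so matched displaced-volume actuation splits
# cleanly across pump units.
#
# One roller: center b(tau) sweeps [x_c - (L_d - w)/2, x_c + (L_d - w)/2] at
# speed c; amplitude envelope sin^2(pi tau) makes the restart C^1 in time.
# Returns the area fraction occ = 1 - (a/r0)^2 and its exact t/x/xt partial
# derivatives.
pump_occlusion <- function(pump, x, t) {
  w  <- pump$deformation_length_m / 2
  Tp <- pump_period(pump)
  span <- pump$deformation_length_m - w
  psi <- pump$occlusion * (2 - pump$occlusion)
  c0 <- pump$wave_speed_m_s
  occ <- occ_t <- occ_x <- occ_xt <- numeric(length(x))
  for (k in seq_len(pump$n_rollers)) {
    tau <- ((t / Tp + pump$phase / (2 * pi) + (k - 1) / pump$n_rollers) %% 1)
    E  <- sin(pi * tau)^2
    Ed <- pi * sin(2 * pi * tau) / Tp          # dE/dt
    b  <- pump$center_m - span / 2 + span * tau
    B   <- bump_profile(x - b, w)
    Bd  <- bump_profile_d(x - b, w)
    Bdd <- bump_profile_dd(x - b, w)
    occ    <- occ + psi * E * B
    occ_t  <- occ_t + psi * (Ed * B - E * Bd * c0)
    occ_x  <- occ_x + psi * E * Bd
    occ_xt <- occ_xt + psi * (Ed * Bd - E * Bdd * c0)
  }
  list(occ = occ, occ_t = occ_t, occ_x = occ_x, occ_xt = occ_xt)
}

# Area-occlusion field for the sine_train waveform over the whole tube:
# occ = (psi/2) (1 - cos(2 pi (x - c t) / lambda)).
train_occlusion <- function(config, x, t) {
  p <- config$pumps[[1]]
  psi <- p$occlusion * (2 - p$occlusion)
  lam <- config$wavelength_m
  c0 <- p$wave_speed_m_s
  ph <- 2 * pi * (x - c0 * t) / lam
  occ <- (psi / 2) * (1 - cos(ph))
  occ_x <- (psi / 2) * sin(ph) * (2 * pi / lam)
  occ_t <- -c0 * occ_x
  occ_xt <- -c0 * (psi / 2) * cos(ph) * (2 * pi / lam)^2
  list(occ = occ, occ_t = occ_t, occ_x = occ_x, occ_xt = occ_xt)
}

config_occlusion <- function(config, x, t) {
  if (config$waveform == "sine_train") {
    o <- train_occlusion(config, x, t)
  } else {
    occ <- occ_t <- occ_x <- occ_xt <- numeric(length(x))
    for (p in config$pumps) {
      o <- pump_occlusion(p, x, t)
      occ <- occ + o$occ; occ_t <- occ_t + o$occ_t
      occ_x <- occ_x + o$occ_x; occ_xt <- occ_xt + o$occ_xt
    }
    o <- list(occ = occ, occ_t = occ_t, occ_x = occ_x, occ_xt = occ_xt)
  }
  if (any(o$occ >= 1 - 0.05^2))
    stop("combined occlusion beyond 0.95 radius fraction: tube nearly ",
         "closed (singular lubrication resistance)", call. = FALSE)
  o
}

# Wall kinematics derived from the area occlusion: radius a, wall velocity
# da/dt, wall slope da/dx, area source S = d(pi a^2)/dt, and d(da/dx)/dt.
wall_kinematics <- function(config, x, t) {
  o <- config_occlusion(config, x, t)
  r0 <- config$tube$inner_radius_m
  a <- r0 * sqrt(1 - o$occ)
  adot <- -r0^2 * o$occ_t / (2 * a)
  aslope <- -r0^2 * o$occ_x / (2 * a)
  aslope_t <- -(r0^2 / 2) * (o$occ_xt / a - o$occ_x * adot / a^2)
  list(a = a, adot = adot, aslope = aslope, aslope_t = aslope_t,
       S = -pi * r0^2 * o$occ_t)
}

check_in_tube <- function(config, x) {
  if (any(x < 0 | x > config$tube$length_m))
    stop("x outside the tube [0, ", config$tube$length_m, "] m", call. = FALSE)
}

#' Inner-radius field a(x, t)
#'
#' The time-dependent inner radius of the tube under the traveling roller
#' occlusion. Equals the undeformed radius `r0` outside every pump footprint;
#' inside a footprint a raised-cosine squeeze of width `L_d / 2` (applied to
#' the cross-sectional area, so the displaced-volume rate is linear in the
#' occlusion amplitude) travels at the roller speed with a smooth amplitude
#' envelope, reaching the minimum radius `(1 - occlusion) * r0` at the
#' deepest instant of each cycle. The field is continuously differentiable
#' in `x` and `t`.
#'
#' @param config A [cascade_config()].
#' @param x Axial positions, meters, inside `[0, L]`. Vectorized.
#' @param t Time, seconds (scalar).
#' @return Inner radius in meters, same length as `x`.
#' @seealso [occlusion_rate()] for the exact wall velocity `da/dt`.
#' @export
#' @examples
#' cfg <- cascade_config(tube_spec(), list(pump_unit(0.1, occlusion = 0.5)))
#' radius_field(cfg, c(0.05, 0.1), t = 0.2)
radius_field <- function(config, x, t) {
  check_in_tube(config, x)
  wall_kinematics(config, x, t)$a
}

#' Wall velocity da/dt
#'
#' Exact analytic time derivative of [radius_field()] (not a finite
#' difference). Zero outside pump footprints; integrates to zero over one
#' roller period at every `x`.
#'
#' @inheritParams radius_field
#' @return `da/dt` in m/s, same length as `x`.
#' @export
occlusion_rate <- function(config, x, t) {
  check_in_tube(config, x)
  wall_kinematics(config, x, t)$adot
}

# Axial slope da/dx (exact), used by the velocity-field reconstruction.
radius_slope <- function(config, x, t) {
  check_in_tube(config, x)
  wall_kinematics(config, x, t)$aslope
}
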