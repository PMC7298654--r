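#' Newtonian fluid
#'
#' Constant-viscosity fluid. The default (1 Pa s, 1000 kg/m^3) is the order of
#' magnitude of a 5-6 % (w/v) gelatin sol; in the Stokes regime all
#' single-versus-dual comparisons are viscosity-insensitive ratios, so the
#' absolute value mainly sets the pressure scale.
#'
#' @param viscosity_pa_s Dynamic viscosity, Pa s (> 0).
#' @param density_kg_m3 Density, kg/m^3 (> 0). Carried for completeness;
#'   inertia is neglected throughout (Re << 1).
#' @return An object of class `c("newtonian_fluid", "fluid_model")`.
#' @export
newtonian_fluid <- function(viscosity_pa_s = 1.0, density_kg_m3 = 1000) {
  stopifnot(viscosity_pa_s > 0, density_kg_m3 > 0)
  structure(list(viscosity_pa_s = viscosity_pa_s,
                 density_kg_m3 = density_kg_m3),
            class = c("newtonian_fluid", "fluid_model"))
}

#' Shear-thinning power-law fluid
#'
#' Ostwald-de Waele model: apparent viscosity `K * shear_rate^(n - 1)`,
#' clamped at a floor shear rate to keep the viscosity bounded on the tube
#' axis. `n = 1` reproduces the Newtonian model exactly.
#'
#' @param consistency Consistency index K, Pa s^n (> 0).
#' @param index Flow behavior index n in (0, 1] (shear-thinning or Newtonian
#'   limit).
#' @param density_kg_m3 Density, kg/m^3.
#' @param floor_shear_s Floor shear rate, 1/s; rates below it are clamped.
#' @return An object of class `c("power_law_fluid", "fluid_model")`.
#' @export
power_law_fluid <- function(consistency = 1.0, index = 0.5,
                            density_kg_m3 = 1000, floor_shear_s = 1e-3) {
  stopifnot(consistency > 0, index > 0, index <= 1, floor_shear_s > 0)
  structure(list(consistency = consistency, index = index,
                 density_kg_m3 = density_kg_m3,
                 floor_shear_s = floor_shear_s),
            class = c("power_law_fluid", "fluid_model"))
}

#' Time-gelling fluid
#'
#' A phenomenological model of a slowly cross-linking solution (e.g. gelatin
#' with transglutaminase): a power-law base whose viscosity is multiplied by
#' a logistic function of the material age, rising from 1 to the plateau
#' multiplier around the gelation onset time. Only the rise-to-plateau
#' envelope of the measured transient is modeled, not the early non-monotone
#' dip.
#'
#' @param base A [power_law_fluid()] (use `index = 1` for a Newtonian base).
#' @param plateau_mult Plateau viscosity multiplier `m_inf >= 1` (gel/sol
#'   apparent-viscosity ratio).
#' @param onset_s Gelation onset time, seconds. Default 600 s: the enzymatic
#'   sol-gel transition completes on a greater-than-10-minute timescale.
#' @param rise_s Width of the logistic rise, seconds.
#' @return An object of class `c("gelling_fluid", "fluid_model")`.
#' @export
gelling_fluid <- function(base = power_law_fluid(index = 1),
                          plateau_mult = 100, onset_s = 600, rise_s = 120) {
  stopifnot(inherits(base, "power_law_fluid"), plateau_mult >= 1,
            onset_s >= 0, rise_s > 0)
  structure(list(base = base, plateau_mult = plateau_mult,
                 onset_s = onset_s, rise_s = rise_s),
            class = c("gelling_fluid", "fluid_model"))
}

#' Age-dependent viscosity multiplier of a gelling fluid
#'
#' `1 + (m_inf - 1) / (1 + exp(-(age - onset) / rise))`: monotone
#' non-decreasing in age, bounded by the plateau multiplier.
#'
#' @param fluid A [gelling_fluid()].
#' @param age_s Material age(s), seconds, >= 0.
#' @return Dimensionless multiplier(s) in `[1, m_inf]`.
#' @export
gel_multiplier <- function(fluid, age_s) {
  stopifnot(inherits(fluid, "gelling_fluid"))
  if (any(age_s < 0)) stop("age must be >= 0", call. = FALSE)
  1 + (fluid$plateau_mult - 1) /
    (1 + exp(-(age_s - fluid$onset_s) / fluid$rise_s))
}

#' Apparent viscosity
#'
#' Apparent (generalized-Newtonian) viscosity of a fluid model at a given
#' shear rate and material age. Newtonian: constant. Power-law:
#' `K * max(shear, floor)^(n - 1)`. Gelling: the power-law value times the
#' logistic age multiplier ([gel_multiplier()]).
#'
#' @param fluid A fluid model object.
#' @param shear_rate_s Shear rate(s), 1/s, >= 0.
#' @param age_s Material age(s), seconds, >= 0. Ignored by non-gelling models.
#' @param ... Passed to methods.
#' @return Apparent viscosity in Pa s, recycled to the common length of
#'   `shear_rate_s` and `age_s`.
#' @export
#' @examples
#' apparent_viscosity(power_law_fluid(consistency = 1, index = 0.5), 4)  # 0.5
apparent_viscosity <- function(fluid, shear_rate_s, age_s = 0, ...) {
  if (any(shear_rate_s < 0)) stop("shear rate must be >= 0", call. = FALSE)
  if (any(age_s < 0)) stop("age must be >= 0", call. = FALSE)
  UseMethod("apparent_viscosity")
}

#' @export
apparent_viscosity.newtonian_fluid <- function(fluid, shear_rate_s,
                                               age_s = 0, ...) {
  rep_len(fluid$viscosity_pa_s, max(length(shear_rate_s), length(age_s)))
}

#' @export
apparent_viscosity.power_law_fluid <- function(fluid, shear_rate_s,
                                               age_s = 0, ...) {
  g <- pmax(shear_rate_s, fluid$floor_shear_s)
  rep_len(fluid$consistency * g^(fluid$index - 1),
          max(length(shear_rate_s), length(age_s)))
}

#' @export
apparent_viscosity.gelling_fluid <- function(fluid, shear_rate_s,
                                             age_s = 0, ...) {
  base <- apparent_viscosity(fluid$base, shear_rate_s)
  mult <- gel_multiplier(fluid, age_s)
  out <- base * mult
  rep_len(out, max(length(shear_rate_s), length(age_s)))
}

# Density accessor (gelling fluid inherits its base density).
fluid_density <- function(fluid) {
  if (inherits(fluid, "gelling_fluid")) return(fluid$base$density_kg_m3)
  fluid$density_kg_m3
}

#' @export
print.fluid_model <- function(x, ...) {
  cls <- class(x)[1]
  if (cls == "newtonian_fluid")
    cat(sprintf("<newtonian_fluid> mu = %g Pa s\n", x$viscosity_pa_s))
  else if (cls == "power_law_fluid")
    cat(sprintf("<power_law_fluid> K = %g Pa s^n, n = %g\n",
                x$consistency, x$index))
  else
    cat(sprintf(
      "<gelling_fluid> base K = %g, n = %g; plateau x%g, onset %g s, rise %g s\n",
      x$base$consistency, x$base$index, x$plateau_mult, x$onset_s, x$rise_s))
  invisible(x)
}
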