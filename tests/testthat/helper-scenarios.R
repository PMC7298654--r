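# Shared builders for the test suite. Geometry follows the reference study
# conditions: 1 m tube, 1.6 mm inner diameter, 4 cm deformation length.

single_config <- function(occlusion = 0.5, ...) {
  cascade_config(tube_spec(), list(pump_unit(0.1, occlusion = occlusion, ...)))
}

dual_config <- function(occlusion = 0.25, centers = c(0.1, 0.5), ...) {
  cascade_config(tube_spec(), lapply(centers, function(xc)
    pump_unit(xc, occlusion = occlusion, ...)))
}

quick_solve <- function(config, fluid = newtonian_fluid(), periods = 2,
                        steps_per_period = 48, ...) {
  solve_flow(config, fluid, periods = periods,
             steps_per_period = steps_per_period, ...)
}
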