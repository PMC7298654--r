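# peripump

Single versus cascade peristaltic pumping of viscous and slowly gelling
fluids in narrow tubes: a lubrication-theory simulator with shear-exposure
analysis and a clogging model.

## The problem

Shaping gel fibers *online* — inside the flowing tube, before extrusion —
is attractive for microextrusion bioprinting of slowly cross-linking
materials such as gelatin/transglutaminase solutions, but the sol–gel
transition takes ten minutes or more. Driving such a fluid through a long
narrow tube with a single peristaltic pump accumulates hydraulic
resistance until the channel clogs, and concentrates all actuation at one
location, producing locally intense shear that harms encapsulated cells.
Cascade pumping splits the load over several pumping units in series on
one tube (multiple channels of one roller pump). This package is for
researchers who want to quantify that trade-off: it simulates both
configurations under matched actuation and reports the flow, pressure and
shear environment, and the time to clog for a gelling fluid.

## Model core

Axisymmetric long-wavelength (lubrication) flow with a prescribed
traveling-occlusion wall, solved per time level by quadrature:

    d(pi a^2)/dt + dQ/dx = 0,      dp/dx = -8 mu_app Q / (pi a^4),

with reservoir ends `p(0,t) = p(L,t) = 0` and a generalized
(Rabinowitsch) closure for power-law fluids. From the solution the
meridional velocity field `(u, v)` is reconstructed (parabolic profile
carrying the local flow rate; radial velocity from the exact continuity
integral), and all nine velocity gradients feed the total shear-rate
magnitude

    |gamma| = [ 2 u_x^2 + 2 v_y^2 + 2 w_z^2 + (v_x + u_y)^2
                + (w_y + v_z)^2 + (u_z + w_x)^2 ]^(1/2)

under a recorded out-of-plane substitution convention (see the methods
vignette), together with the in-plane shear rate `eps = u_y + v_x` and the
extensional strain rate `eta = u_x + v_y`. A lumped residence-time model
advects the material age, converts it to apparent viscosity, and throttles
the flow against the pumps' pressure capacities to detect clogging.

## Worked example

Calibrate the reference single-pump scenario (1 m tube, inner diameter
1.6 mm, pump at 0.1 m, 4 cm deformation length) so its maximum in-plane
shear rate is 885 1/s, then compare it with the dual-pump scenario
(pumps at 0.1 m and 0.5 m) at equal total actuation:

```r
library(peripump)
presets <- cascade_presets()
single  <- realize_scenario("single_0.1", presets)
sol     <- solve_flow(single, periods = 2, discard = 3)
summary(sol)
#> Cycle-averaged summary over 2 period(s):
#>   net flow      7.362e-10 m^3/s
#>   peak |Q|      3.537e-08 m^3/s (peak/net = 48)
#>   peak pressure 1.943e+04 Pa

rep_s <- shear_report(sol)
rep_s
#> <shear_report> 1 pump(s), convention = paper_substitution
#>   pump 0.10 m (phi 0.5348): xy max eps 883.6, eta 19.53, |gamma| 1250 1/s; yz max |gamma| 1250
#>   max pressure 1.943e+04 Pa, net flow 7.362e-10 m^3/s

A     <- pump_actuation(sol, 1)$displacement_m3_s
dual  <- realize_scenario("dual_0.1_0.5", presets, reference_actuation = A)
rep_d <- shear_report(solve_flow(dual, periods = 2, discard = 3))
compare_conditions(list(single = rep_s, dual = rep_d))
#>      metric plane scenario max_value ratio_to_first fold_reduction
#> 9     gamma    xy   single 1.250e+03          1.000         0.0000
#> 10    gamma    xy     dual 1.398e+02          8.939         7.9387
#> 13 pressure axial   single 1.943e+04          1.000         0.0000
#> 14 pressure axial     dual 2.437e+03          7.975         6.9745
```

Reading the numbers: the calibrated single pump squeezes to occlusion
0.535 and produces a total shear-rate maximum of 1250 1/s (the factor
√2 ≈ 1.414 above the 884 1/s in-plane anchor comes from the substitution
convention in the nine-gradient norm). Splitting the same total displaced
volume over two units cuts the per-unit squeeze to occlusion 0.220, the
shear maximum by a factor of ~8.9 and the peak pressure by a factor of
~8.0; peak flow at the pump halves (`peak_flow()`).

For a gelling fluid, `simulate_transit()` tracks the mean flow against
the growing resistance and reports the clog time;
`compare_configurations()` tabulates single versus cascade runs.

A thin command-line front end over the same functions is installed at
`inst/cli/peripump.R` (subcommands `simulate`, `shear-report`, `clogging`,
`compare`, reading YAML scenario files; see `load_config()`).

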