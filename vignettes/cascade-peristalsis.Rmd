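---
title: "Cascade peristaltic pumping: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascade peristaltic pumping: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peripump)
```

## The problem

In microextrusion bioprinting, slowly cross-linking materials such as
gelatin/transglutaminase solutions must be kept moving through a narrow
tube for ten minutes or more while they gel. Two things go wrong in a long
tube driven by a single peristaltic pump: the hydraulic resistance of the
progressively gelling fluid accumulates until the channel clogs, and the
single pump must impose all of the actuation at one location, generating
locally intense shear that damages encapsulated cells. Cascade pumping —
several pumping units in series along one tube, inside one multi-channel
roller pump — splits the actuation load. `peripump` simulates both
configurations and quantifies the flow, pressure and shear environment, and
the clogging behavior, so the two strategies can be compared under matched
actuation.

## Flow model

The tube (length $L = 1$ m, inner radius $r_0 = 0.8$ mm by default) is
axisymmetric, and each pump unit deforms a 4 cm "shoe" segment. The ratio
of radius to deformation length is $0.8\,\mathrm{mm} / 4\,\mathrm{cm} =
0.02$, so the flow is deep in the lubrication (long-wavelength) regime, and
with viscosities of order 1 Pa s the Reynolds number is far below one.
Under these conditions the incompressible flow reduces, at each instant, to

$$\frac{\partial (\pi a^2)}{\partial t} + \frac{\partial Q}{\partial x} = 0,
\qquad
\frac{\partial p}{\partial x} = -\frac{8 \mu_{\mathrm{app}} Q}{\pi a^4},$$

with reservoir conditions $p(0, t) = p(L, t) = 0$. Because the wall motion
$a(x, t)$ is prescribed, each time level is an independent one-dimensional
quadrature problem: the continuity equation gives $Q(x) = Q_0 -
\int_0^x \partial_t(\pi a^2)\,dx'$, and $Q_0$ follows from the zero net
pressure rise across the tube. For power-law fluids the closure is the
generalized (Rabinowitsch) form
$\partial p/\partial x = -(2K/a)\,[(3n{+}1)\,|Q| / (n \pi a^3)]^{n}\,
\mathrm{sign}(Q)$, and $Q_0$ is found by a monotone root solve. Mass
conservation therefore holds to machine precision on the solver grid
(`continuity_residual()` audits it), and the end pressures are zero by
construction.

The model is **quasi-static**: time enters only through the prescribed wall
motion, which is exact in the Stokes limit. A consequence worth knowing is
that all velocities scale linearly with the roller speed, so ratios such as
peak-to-mean flow depend only on the waveform geometry and occlusion depth.

## The occlusion waveform

Roller kinematics are not observable from the study conditions, so the
waveform is a documented design choice:

* Each roller produces a raised-cosine squeeze of width $w = L_d/2$
  (2 cm). The squeeze is applied to the **cross-sectional area**,
  $\pi a^2 = \pi r_0^2 (1 - \psi E B)$, with amplitude $\psi =
  \phi(2-\phi)$ chosen so the minimum radius at the deepest instant is
  exactly $(1-\phi) r_0$, where $\phi$ is the user-facing occlusion
  fraction. Parameterizing the area makes the displaced-volume rate exactly
  linear in the amplitude, so "half the actuation" literally halves the
  wall source — the bookkeeping that underlies every matched-actuation
  comparison. A radius-parameterized cosine was tried first and makes the
  source sublinear in $\phi$, distorting the split.
* The roller center sweeps the interior of the shoe at the roller speed
  $c$ and restarts each cycle, with a $\sin^2$ amplitude envelope so the
  restart is continuously differentiable in time; the cycle period is
  $(L_d - w)/c = L_d/(2c)$. The squeeze support never leaves the 4 cm
  footprint, and the radius field is $C^1$ in both $x$ and $t$.
* **Two rollers per shoe** (staggered by half a cycle) are the default.
  Their $\sin^2$ envelopes sum to a constant, so the shoe's total occluded
  volume does not pulsate — exactly like a physical roller pump, which
  always keeps one roller engaged. A single engaging/disengaging roller
  (`n_rollers = 1`) is available, but its pulsating engagement drives a
  large non-propulsive slosh through the nearest reservoir that dominates
  the peak flow and pressure readings.
* Default roller speed $c = 0.025$ m/s. The free amplitude is fixed by a
  shear anchor (below); given that anchor, $c$ controls where the
  peak-to-steady flow ratio lands, and 0.025 m/s places the anchored
  reference scenario at a ratio of about 48, inside the expected
  one-to-two orders of magnitude band.

## Rheology

Three generalized-Newtonian models supply the apparent viscosity:

* `newtonian_fluid(viscosity_pa_s = 1, density_kg_m3 = 1000)` — the
  default simulation fluid, the order of magnitude of a 5–6 % (w/v)
  gelatin sol. All headline comparisons are single-versus-dual ratios,
  which are viscosity-insensitive in the Stokes regime.
* `power_law_fluid(consistency, index)` — shear-thinning
  Ostwald–de Waele, with a floor shear rate (default $10^{-3}$ 1/s) so the
  viscosity stays bounded on the tube axis. `index = 1` reproduces the
  Newtonian model exactly.
* `gelling_fluid(base, plateau_mult, onset_s, rise_s)` — the power-law
  value times a logistic function of the material age,
  $1 + (m_\infty - 1)/(1 + e^{-(\tau - t_{\mathrm{on}})/t_{\mathrm{rise}}})$.
  Defaults: onset 600 s (the enzymatic sol–gel transition completes on a
  longer-than-ten-minute timescale), rise 120 s (the transition spread over
  a few minutes), plateau multiplier 100 (a gel two orders of magnitude
  more resistive than the sol — the qualitative gel/sol contrast, not a
  fitted value). Only the rise-to-plateau envelope is modeled; the early
  non-monotone transient seen in rheometry (a rise and dip before the
  plateau) is deliberately not.

## Shear metrics and the substitution convention

The meridional velocity field is reconstructed from the lubrication
solution on a body-fitted grid $(x, \sigma)$, $\sigma = y/a \in [-1, 1]$:
the axial profile is the parabola carrying the local flow rate, and the
radial velocity is the exact continuity integral, which matches the wall
velocity at $y = \pm a$ identically. Gradients are taken by central
differences (second-order one-sided at boundaries) in computational
coordinates and mapped back through the chain rule.

The three scalar metrics are the in-plane shear rate $\varepsilon =
\partial u/\partial y + \partial v/\partial x$, the extensional strain rate
$\eta = \partial u/\partial x + \partial v/\partial y$, and the total
shear-rate magnitude

$$|\dot\gamma| = \Big[\, 2 u_x^2 + 2 v_y^2 + 2 w_z^2 + (v_x + u_y)^2 +
(w_y + v_z)^2 + (u_z + w_x)^2 \,\Big]^{1/2},$$

assembled from all nine velocity gradients. For axisymmetric tube flow the
azimuthal component in cylindrical coordinates vanishes; the field's
practice in comparable analyses, however, is to treat the out-of-plane
component as commensurate with the radial one and substitute it
accordingly. Both options are implemented as a recorded convention flag:

* `paper_substitution` (default): $w := v$ and every $z$-derivative is
  replaced by its $y$-analogue ($u_z := u_y$, $w_x := v_x$, $w_y := v_y$,
  $w_z := v_y$, $v_z := v_y$). Where wall shear dominates this gives
  $|\dot\gamma| \approx \sqrt{2}\,|\varepsilon|$, which is the
  $\approx$1.45 ratio between total-magnitude and in-plane maxima that the
  calibrated scenarios reproduce.
* `true_axisymmetric`: the exact cylindrical entries ($w = 0$,
  $w_z = v/y$ with the axis limit $v_y$), for which a parabolic profile
  gives $|\dot\gamma| = |u_y|$.

Maxima are reported at the deepest-occlusion instant of the cycle (the
instant is recorded in the report). Frequency distributions are
**area-weighted**: meridional cells by their physical cell area, transverse
(yz) samples by their annulus area, so resampling the disk on a Cartesian
grid cannot bias the histogram. Whether node-count or area weighting is
used upstream of comparable published histograms is not stated anywhere we
could check; area weighting is the physically meaningful choice and is
flagged in the report metadata. The default bin width is 100 1/s, matching
the conventional 100 and 600 1/s exposure breakpoints.

## Calibration and scenario linkage

The study conditions fix the geometry but not the actuation amplitude, so
scenarios are calibrated rather than parameterized directly
(`calibrate_occlusion()`, bisection on a shared occlusion with bracket
verification, 0.2 % matching tolerance):

* the **single** scenario anchors its maximum in-plane shear rate at
  885 1/s, the one printed anchor available for the reference comparison;
* the **dual** scenario is linked by *equal total actuation*: the same
  total cycle-averaged displaced-volume rate, split equally over the two
  units. "Identical power supply" is operationalized as displaced volume
  (mechanical power is also reported by `pump_actuation()`) because the
  stated consequences — peak flow roughly twice as high under single
  pumping, shear reduced by more than one fold — follow from a 2:1 split
  of volumetric actuation;
* a third target, matched **mean flow**, pairs scenarios by delivered net
  flow; it is the right pairing for comparing pressure profiles in the
  shared downstream segment, where both scenarios then agree to well
  within 5 %.

The peak flow rate "at the pump" is read as the maximum pumping-direction
flow rate over the footprint and cycle (`peak_flow(..., "forward")`); the
absolute-value peak additionally picks up a backward recirculation
transient whose size depends on squeeze depth and is not what a flow-rate
profile peak reports.

## Gelation and clogging

The gelation timescale (minutes) exceeds the pump cycle (sub-second) by
more than three orders of magnitude, so the transit model
(`simulate_transit()`) is quasi-static: the fast cycle supplies a target
mean flow and per-pump pressure capacities; on the slow timescale the
material age advects downstream (first-order upwind, CFL-checked,
$\partial\tau/\partial t + \bar u\,\partial\tau/\partial x = 1$ with inlet
age zero), sets the local apparent viscosity, and with it the series
resistance $8\mu\,dx/(\pi r_0^4)$. The flow is throttled to
$Q = \min(Q_{\mathrm{set}},\ \sum_i p_{\mathrm{cap},i} / R_{\mathrm{tot}})$,
and a clog is declared when $Q$ first falls below 10 % of its initial
value (the reference observations are qualitative, so the threshold is a
convention). Intermediate node pressures are left unconstrained — a
peristaltic unit can hold suction — so capacities in series add; at equal
*total* capacity, single and cascade configurations are then exactly
equivalent, and the cascade's advantage is that total capacity scales with
the number of units at fixed per-channel hardware. Per-pump loads are
reported against the natural segment split (each unit covers the tube from
its own position to the next unit), under which the dual units each carry
half the single unit's demand.

## Numerical defaults and problem sizes

* Axial solver grid: 801 nodes for the 1 m tube (32 per deformation
  length; at least 20 per deformation length is enforced). Each instant is
  a quadrature solve, so a full run (64 steps per cycle, 3 discarded + 2
  analyzed cycles) takes well under a second.
* Shear windows: 241 × 81 body-fitted nodes over 1.5 deformation lengths
  around each pump, with the tube-wide quadrature for $Q_0$ on a 2001-node
  grid at the analysis instant. Reported maxima move by less than 0.1 %
  when both grid directions are doubled.
* Occlusions above 0.95 are rejected (the $a^{-4}$ resistance would make
  the problem numerically singular); calibration brackets within
  $\phi \in [0.02, 0.94]$.
* Transit model: 201 axial nodes, slow step at half the CFL limit of the
  initial mean flow.

## What the scenarios do and do not emulate

The built-in presets (`cascade_presets()`) reproduce the reference study
conditions exactly: 1 m tube, 1.6 mm inner diameter, 4 cm deformation
length, single pump at 0.1 m, dual pumps at 0.1/0.5 m, and the
secondary-pump sweep at 0.2/0.3/0.4/0.5 m with the first pump fixed at
0.1 m. What they cannot emulate is anything that depended on the original
unpublished finite-element setup: the material constants, deformation
amplitude and mesh are unknown, so absolute pressures and velocities from
this package are model quantities, not predictions of those simulations.
The package therefore reports and tests *calibrated* quantities (plane
maxima under the 885 and 435 1/s anchors) and *ratios* (fold differences
under matched actuation), which are insensitive to the unknown absolutes.

Known limitations, by construction: no wall compliance outside the pump
shoe, no fluid inertia, no azimuthal (swirl) component, no reconstruction
fidelity beyond lubrication accuracy inside the occluded gap, no
viscoelasticity, and no spatially resolved gel front — the clogging model
is a lumped series network validated by orderings and invariants, not by
quantitative clog times.

## A short session

```{r example, eval = FALSE}
presets <- cascade_presets()
single <- realize_scenario("single_0.1", presets)
sol <- solve_flow(single, periods = 2, discard = 3)
summary(sol)
shear_report(sol)
```
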