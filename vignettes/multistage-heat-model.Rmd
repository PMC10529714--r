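---
title: "Modelling multistage heating and cooling of salted-smoked pork loin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling multistage heating and cooling of salted-smoked pork loin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loinheat)
```

## The problem

Industrial production of salted-smoked pork loin ("Hamburgerryg") runs a
large cylindrical piece of cured meat through a fixed sequence of thermal
operations: drying and smoking in a hot-air chamber, a transfer through
ambient air, steam-cooking, water-cooling by spray in the same chamber, a
second transfer, and a long air-cooling in a chill room. Food safety is
governed by the *cold spot* — the location of the field minimum — during
heating (it must reach pasteurization temperature, about 72 °C), and by the
*hot spot* during cooling. Neither can be watched with a physical probe,
because they move: the cold spot sits at the product centre while heating
and jumps to the surface when cooling starts. `loinheat` provides a forward
model of the whole multistage process, tools to estimate the uncertain
surface heat-transfer coefficients from temperature-logger data, and a
synthetic-logger generator so that the calibration machinery is testable
without proprietary plant data.

## Model

Within the product, heat moves by conduction with constant effective
properties:

$$\rho_m c_{p,m} \frac{\partial T}{\partial t} = \nabla \cdot (k_m \nabla T).$$

Mass transfer is neglected: the fibre casing keeps moisture loss below a
few percent over the whole process, so latent-heat effects are second
order. The product is a cylinder (default D = 0.085 m, L = 0.54 m), treated
axisymmetrically and halved at the mid-plane, leaving the rectangle
$(r, z) \in [0, R] \times [0, L_h]$ with zero flux on the axis and
mid-plane.

Every stage exchanges heat with its medium through the same convective
(Robin) condition on the lateral surface and end face,

$$-\mathbf{n} \cdot (k_m \nabla T) = h(t)\,\big(T_p(t) - T_s\big),$$

where both the coefficient $h$ and the medium temperature $T_p$ are
piecewise constant in time: the entire process is a schedule of
$(\text{duration}, T_p, h)$ triples. The packaged defaults are the
industrial scenario (durations 6300 + 6300, 1200, 7920, 7200, 1200,
54000 s; $h$ = 20, 20, 8, 2000, 80, 8, 12 W/(m² K); media at 333.15,
318.15, 298.15, 351.15, 298.15, 298.15, 276.15 K; initial temperature
280.65 K). The recipe fixes only the *combined* drying-smoking time
(12600 s); its split is an assumption, equal halves by default, exposed in
the configuration and consistency-checked. Stage windows are half-open
`[start, end)` with the final instant included, so `h(t)` and `Tp(t)` are
deterministic and switch jointly at the same instants.

## Thermophysical properties

Effective properties come either directly from configuration (the default
scenario uses the typical product values 1064.5 kg/m³, 3535.5 J/(kg K),
0.47 W/(m K)) or from a proximate composition via standard mixture rules
over water, protein, fat, carbohydrate and ash:

* density — harmonic mass-fraction mean, $\rho_m = 1/\sum_i x_i/\rho_i$;
* specific heat — arithmetic mass-fraction mean,
  $c_{p,m} = \sum_i x_i c_{p,i}$;
* conductivity — a weighted blend of the volume-fraction parallel
  (arithmetic) and perpendicular (harmonic) bounds,
  $k_m = g\,k_{per} + (1-g)\,k_{par}$, which always satisfies
  $k_{per} \le k_m \le k_{par}$.

Component constants are Choi-Okos-type polynomial values evaluated at
20 °C, a mid-process reference ([component_property_table()]); properties
are held temperature-independent through the run, matching the use of a
single typical value per property in the underlying scenario. The blending
weight $g$ is not part of the published scenario; the package defaults to
$g = 0.5$, the midpoint of the physical bounds. The default composition
(72.6 % water, 18.2 % protein, 4.3 % fat, 0.6 % carbohydrate, 4.3 % ash —
the ash reflecting curing salt) was calibrated once, by the recorded script
`scripts/calibrate_composition.R`, so that the three estimators reproduce
the typical product values within 0.5 %; the exact-fit composition was
rejected in favour of one constrained toward a realistic cured-loin
proximate analysis, since three targets under-determine five fractions.

## Numerical solution

Space is discretized with conservative, vertex-centred finite volumes on a
uniform `(r, z)` grid (default 45 × 90 nodes). Radial cell volumes are
exact integrals of $r\,\mathrm{d}r$, so the axis singularity never appears;
the scheme is second order, and the discrete operator is symmetric, which
makes the implicit systems positive definite and lets every step reuse a
sparse Cholesky factorization.

Time integration restarts at every stage boundary, because $h$ jumps by up
to two orders of magnitude (8 → 2000 W/(m² K)) between stages. Each stage
opens with two backward-Euler steps of `dt_init` (1 s) to damp the
boundary-condition discontinuity (a Rannacher start), then Crank-Nicolson
steps grow geometrically to `dt_max` (30 s). Probe and summary series are
reported on a fixed 60 s grid — the logger cadence — by linear
interpolation between accepted steps; stage boundaries and requested
snapshot times are forced to be exact step endpoints.

Three verifications back the solver:

* **Analytic oracle.** For a single constant-coefficient stage the exact
  solution is the product of the infinite-cylinder and symmetric-slab
  Robin-boundary eigenfunction series; `analytic_finite_cylinder()`
  implements it independently (eigenvalues by sign-scan bracketing and
  `uniroot`). On the default grid the centre series agrees to better than
  0.1 K for t ≥ 300 s, and halving the grid spacing cuts the error about
  fourfold.
* **Energy accounting.** Each step adds its boundary-flux quadrature
  (matching the step's own θ-weighting) to a per-stage ledger; because the
  scheme is conservative, the stage's internal-energy change equals the
  integrated flux to round-off, and the suite asserts 0.5 %.
* **Maximum principle.** Over the full default run all nodal temperatures
  stay inside the span of the initial and medium temperatures
  (276.15-351.15 K) within 10⁻³ K.

Numerical defaults worth knowing: extremum locations are reported at grid
nodes with ties broken toward the smallest radial then axial index; the
axial interior of this long cylinder is nearly isothermal, so cold-/hot-spot
*z*-coordinates within the interior carry little information (the tests
therefore assert interior-versus-boundary, not exact coordinates);
`store_fields = TRUE` keeps the full field at every output sample, which is
what [probe()] needs to interpolate at points not declared beforehand —
at the default grid this costs ~45 MB, so declare `probe_points` up front
for production-size runs.

## Calibration

The water-cooling and air-cooling coefficients are plant-specific and are
estimated from a centre-probe logger series by least squares
([fit_coefficients()]). Residuals are evaluated only from the start of the
earliest stage a free parameter influences — earlier residuals are
constant in the parameters and would only add noise — and the forward
solution up to that point is computed once and reused across objective
evaluations. The minimizer is a small bounded Levenberg-Marquardt on the
residual vector (forward-difference Jacobian, damping grown until descent,
steps clipped to bounds: $h_w \in [1, 500]$, $h_{air} \in [0.5, 100]$
W/(m² K), initial guesses at half the schedule values). The fit is
deterministic given the data; every objective evaluation is recorded, and
the accepted subsequence is non-increasing.

Identifiability is screened by sensitivity: each fitted parameter is
perturbed to 0.5× and 1.5× its estimate and the maximum change of the
predicted series is compared to a 1 K threshold. This threshold is the
same physical statement as the steam-stage observation that motivates not
fitting $h_{st}$: at $Bi = h R / k \gg 1$ the centre temperature is
insensitive to the surface coefficient, and ±50 % perturbations of
$h_{st}$ move the steam-stage centre series by well under 1 K.

## Synthetic loggers: what they emulate, and what they do not

The industrial experiment placed 16 loggers at the product centre across 4
pallets × 4 layers. `generate_loggers()` reproduces that structure with
three effects:

* a layer-dependent water-temperature offset (+ΔT at the bottom layer 3,
  −ΔT at the top layer 10, linear in layer index; default ΔT = 5 K, the
  "25 ± 5 °C" scenario) — the spray water warms as it descends the pallet,
  so top products cool faster;
* a uniform per-pallet offset of the drying/smoking medium temperature
  (default ±2 K, alternating by pallet) emulating airflow differences
  between pallet positions — illustrative, as the plant data do not
  quantify it;
* iid Gaussian measurement noise, default σ = 0.5 K, a SmartButton-class
  logger resolution.

Ground truth (coefficients and offsets) rides along in each dataset's
metadata, so recovery studies can close the loop: with zero offsets and
σ = 0.5 K, twenty seeded replicate fits recover $h_w = 80$ and
$h_{air} = 12$ with median error well under 5 %, and the noise-free fit is
exact to optimizer tolerance. When positional offsets are on, recovery
requires fitting against the probe's true effective schedule (available
from the metadata); fitting a perturbed probe against the nominal schedule
confounds the water-temperature offset with $h_w$, which is a real feature
of the inverse problem, not an artifact.

The generator does **not** emulate airflow physics, logger drift, dropout
or quantization, or any within-product deviation of the probe from the
exact centre. A green recovery test therefore establishes that the
estimation machinery is correct and well-conditioned at the stated noise
level — not that the industrial validation statistics are reproduced;
those depend on undeposited plant data and are out of reach by
construction.

## Desk-scale choices in the test suite

The acceptance-grade forward run uses the full 45 × 90 grid. Repeated-fit
studies run on a 13 × 20 grid with `dt_max = 240 s`: parameter recovery is
self-consistent (data generated and fitted with the same discretization),
so the coarse grid changes runtimes, not conclusions. The "flat cold-spot
during the second transfer" structure is asserted at plot resolution
(total Tmin variation < 1 K across the 1200 s stage) while the volume
average must keep strictly decreasing at every 60 s sample — the package's
operationalization of a qualitative published observation.

## Known limitations

Temperature-independent properties (no freezing or evaporative terms), no
casing thermal resistance, uniform $h$ over lateral and end surfaces (the
boundary condition is written for the whole surface; end-face-specific
coefficients are not part of the scenario), no mass transfer, and no
chamber-airflow physics. Schedules are data, so arbitrary stage lists
work, but $h$ and $T_p$ cannot vary *within* a stage except by splitting
it.
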