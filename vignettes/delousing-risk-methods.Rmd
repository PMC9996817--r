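---
title: "Methods: from delousing discharge to shrimp risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from delousing discharge to shrimp risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumetox)
```

Salmon farms treat sea-lice infestations by bathing caged fish in
pesticide-dosed water — nominally 2000 ng L⁻¹ of deltamethrin — and then
discharging the treatment water untreated. Deltamethrin is lethal to
northern shrimp (*Pandalus borealis*) at roughly a 1000-fold dilution of
that dose, so the question of how far and how long the discharged plume
stays above ~2 ng L⁻¹ is a question about the viability of shrimp grounds
near farms. `plumetox` implements the full chain needed to answer it at
desk scale: sampler calibration, water-concentration inference, tracer
dispersal, impact metrics, and the laboratory effects analysis that
anchors the lethal threshold.

## Passive-sampler calibration

Silicone-rubber sheets absorb dissolved hydrophobic contaminants; the
absorbed amount integrates exposure over the deployment. Two calibration
quantities are needed.

**Polymer–water partition coefficient.** For very hydrophobic analytes
$K_{pw}$ cannot be measured directly in pure water, so it is measured in
several methanol–water mixtures and extrapolated. The cosolvent model is
deliberately the simplest defensible one — a straight line in methanol
mole fraction,

$$\log_{10} K_{pw}(x) = \beta_0 + \beta_1 x,$$

fitted by ordinary least squares (`fit_cosolvent_regression()`); the
intercept $\beta_0$ is the reported pure-water value. More elaborate
cosolvency models exist, but with 5–10 mixture points there is no basis
for choosing among them, and the linear form keeps the extrapolation
honest. The built-in sampler defaults carry the calibrated values
(deltamethrin: 5.86 on AlteSil, 5.45 on SSP silicone; $K_{pw}$ in L per kg
polymer — mass-based, because detection limits are reported per gram of
polymer).

**Exchange kinetics.** Performance reference compounds (PRCs) preloaded
into the sheet dissipate in situ as $f(t) = e^{-k_e t}$, so each recovered
sampler yields $k_e = -\ln f / t$ (`prc_exchange_coefficient()`).
`pool_prc_kinetics()` transfers PRC kinetics to the analyte assuming a
compound-independent sampling rate $R_s = k_e K_{pw} m$, which implies
$k_{e,\mathrm{analyte}} = k_{e,\mathrm{PRC}} K_{pw,\mathrm{PRC}} /
K_{pw,\mathrm{analyte}}$; an alternative molar-mass-exponent rule is
selectable because the appropriate hydrodynamic scaling is
sampler-geometry dependent. PRCs retaining less than 5% or more than 95%
are excluded: outside that window the retained fraction carries almost no
information about $k_e$.

## Water-concentration inference and duration scenarios

Uptake follows first-order exchange,

$$N(T) = \int_0^T R_s\, c_w(t)\, e^{-k_e (T-t)}\,dt
       \;\xrightarrow{\;c_w \text{ const}\;}\;
       K_{pw}\, m\, c_w\, (1 - e^{-k_e T}),$$

which `water_concentration()` inverts. The forward model
(`gen_pas_uptake()`) integrates piecewise-constant concentration series
exactly (each interval contributes a closed-form exponential term), so the
forward–inverse round trip recovers a constant truth to machine precision
— the package's central internal consistency check, exercised across
$K_{pw} \in [10^3, 10^7]$ and $k_e T \in [0.01, 10]$.

The plume contact time of a field-deployed sampler is unknown: anywhere
from a few hours to the full interval between delousing start and sampler
recovery (3.5 days). In the kinetic regime the absorbed amount fixes only
the product $c_w \cdot t$, so `scenario_table()` reports concentrations
under a set of assumed durations, each row conserving $c_w t$. Reporting
uses round-half-away-from-zero to integer ng L⁻¹ (one decimal for LODs),
and raw values are always retained: for cells whose raw value is an exact
half the integer convention is ambiguous in practice, and downstream users
should prefer `cw_raw`. Every estimate carries a fixed ±50% relative
analytical uncertainty band. The same inversion converts the
polymer-mass-based detection limit (0.04 ng g⁻¹) to water-equivalent LODs
(`lod_water_equivalent()`), which scale as $1/t$ in the kinetic regime.

A note on the kinetic approximation: the general and linear-uptake
inversions differ by a relative $\approx k_e t / 2$, i.e. below 1% only
for $k_e t < 0.02$ and up to ~7% at the edge of the kinetic regime
($k_e t = 0.14$). The package always uses the general form; the linear
form appears only as the $k_e = 0$ fallback.

## Dispersal model

The reference simulations for this problem run a full 3-D unstructured-grid
coastal ocean model. `plumetox` deliberately replaces that with a 2-D
depth-integrated surrogate on a regular square grid, because the headline
products — the cellwise maximum-concentration map and the accumulated
time above threshold — are horizontal maps, and because a desk-scale model
with known ground truth is what makes the rest of the chain testable. The
surrogate solves

$$\partial_t C + \mathbf{u}\cdot\nabla C = D \nabla^2 C - \lambda C$$

with explicit operator splitting: flux-form first-order upwind advection,
centred diffusion, multiplicative decay. First-order upwind is chosen for
positivity, not accuracy: threshold-exceedance maps must never be
contaminated by undershoot oscillations, and the scheme's numerical
diffusion is benign next to the calibrated horizontal diffusivity. The
solver refuses to step outside its stability region
($\max(|u|,|v|)\,\Delta t/\Delta x \le 1$, $D\,\Delta t/\Delta x^2 \le
0.25$) with an error naming the offending ratio. Verified properties:
exact mass conservation with closed boundaries, monotone mass loss with
open (zero-gradient) boundaries, positivity, and < 2% L2 error against the
2-D Gaussian closed form after 100 pure-diffusion steps.

Defaults and their reasoning:

* **Currents** (`flow_field_spec()`): residual drift (5, 0) cm s⁻¹ +
  5 cm s⁻¹ rotating tidal ellipse (M2 period) + AR(1) noise (sd
  1 cm s⁻¹, 3 h decorrelation), spatially uniform. This is the simplest
  structure that makes currents "vary and change direction" while keeping
  speeds in the observed 0–20 cm s⁻¹ coastal range.
* **Releases** (`build_schedule()`): 7 cages treated sequentially at 12-h
  intervals (3 days), instantaneous release when the tarpaulin is lifted
  (no release-profile information exists to justify anything slower),
  2000 ng L⁻¹ in a 19 635 m³ pen (25 m radius closed to 10 m depth),
  i.e. ≈ 39 g active ingredient per cage and ≈ 275 g per treatment —
  consistent with the recorded formulation usage of ~270 g.
* **Transport** (`tracer_params()`): horizontal diffusivity 1 m² s⁻¹ (a
  standard coastal value at 50–100 m resolution; no site value exists),
  zero decay by default (half-life ~17.9 days in water, far slower than
  dilution over a 7-day simulation), mixing depth 10 m (the pen depth),
  hourly snapshots, 7-day duration.
* **Grid**: default runs use dx = 50–100 m over ~10 km domains; the test
  suite uses 6 km / dx = 100 m runs of ≤ 30 h so the whole suite stays
  fast.

What the surrogate does **not** reproduce: site-specific numbers. Extent,
area and exposure durations from the reference 3-D simulations (≈ 4–5 km,
6.4 km², 35 h) depend on real bathymetry and forcing. The package's
dispersal claims are therefore property-based — conservation, positivity,
closed-form limits, monotone area-vs-threshold — plus the qualitative
finding, robust across synthetic current realisations, that the
2 ng L⁻¹ contour reaches far beyond 1 km, i.e. well past the 500 m
regulatory exclusion zone.

## Impact metrics

`area_above()` counts full cells (no sub-cell interpolation — honest at
the resolution the solver actually has); `contour_polygons()` provides the
smooth marching-squares alternative and agrees with the cell count to
within a contour ring. `max_extent()` is the largest distance from the
release point to an exceeding cell centre. The risk arithmetic is
deliberately plain: percent and fold dilution, formulation mass at
10 g L⁻¹ active ingredient (back-derived from the paired 27 L ↔ 270 g and
17.5 L ↔ 175 g figures, overridable), and sediment margins against the
0.33 ng g⁻¹ dw PNEC and 16 ng g⁻¹ dw LC50 references. Censored sediment
values propagate as "≤ LOD" bounds — never as LOD/2 substitutions — so a
censored margin is reported as "at least x-fold below".

## Effects analysis

The laboratory design is five replicate tanks of eight shrimp per dose
(control, 0.0008, 0.04, 2 ng L⁻¹), three 1-h pulses on consecutive days,
14-day recovery. The unit-of-analysis question is genuinely open for such
designs, so both routes are provided: the default pools tanks within a
dose and applies a two-sided exact conditional test to the 2×2 dead/alive
table (full hypergeometric enumeration, validated against an independent
exact-test implementation), and a tank-level randomization test (complete
enumeration of tank assignments when feasible) respects the tank as the
experimental unit. `lethal_threshold()` returns the lowest dose with
p < α and positive excess mortality; with the default synthetic outcomes
(80% mortality at the top dose, none elsewhere) it returns 2 ng L⁻¹, the
value that parameterises the dispersal thresholds. α defaults to 0.05,
with a stricter 0.005 mode available for conservative reporting. Under the
null design (all doses at the control's zero mortality) the rule's type-I
error over 10 000 replicates is 0.

## Synthetic data: what it does and does not show

The generators emulate the *structure* of the study's data — first-order
PRC dissipation with multiplicative (lognormal) noise, linear cosolvent
series, binomial tank mortality, exponential-with-distance sediment
deposition with lognormal patchiness (the few-hundredths to few-tenths
ng g⁻¹ dw range observed within ~500 m of treated pens), tidal+residual
currents — with known parameters, so recovery can be asserted exactly.
They do not emulate matrix effects, co-analyte interference, spatially
sheared currents, resuspension, or dose–response shapes between the tested
doses. Passing tests therefore demonstrate that the *methods* are
implemented correctly and are unbiased under their stated models, not that
field data will match the generators.

## Numerical conventions

* Reporting rounding is half-away-from-zero (`round_half_away()`);
  internal values are never rounded.
* All generators accept a seed and are bit-reproducible; one global seed
  fans out to per-generator child streams, so modules can be re-run
  independently without disturbing each other's draws.
* Degenerate inputs fail loudly with classed errors
  (`plumetox_domain_error`, `plumetox_config_error`,
  `plumetox_data_error`) rather than returning NA.
* Fully dissipated PRCs (retained fraction 0) are rejected: $k_e$ is
  unidentifiable there. Degenerate 2×2 tables (all dead or all alive)
  return p = 1.
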