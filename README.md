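# plumetox

Exposure and risk assessment for pyrethroid bath treatments discharged
from salmon farms.

Sea-lice infestations are treated by bathing caged salmon in
deltamethrin-dosed water (nominally 2000 ng L⁻¹, formulation strength
10 g active ingredient per litre) and then releasing the treatment water
untreated. Deltamethrin kills northern shrimp (*Pandalus borealis*) at
about 2 ng L⁻¹ — a 1000-fold dilution of the treatment dose — so the
discharged plume remains lethal to non-target crustaceans far beyond the
farm. `plumetox` is for ecotoxicologists and coastal managers who need to
quantify that risk: it calibrates silicone-rubber passive samplers,
converts absorbed amounts into water concentrations under alternative
exposure-duration assumptions, simulates the dispersal of sequential
cage releases as a depth-integrated passive tracer, and reduces the
results to impact metrics against the lethal threshold.

## The models at the core

* **Passive-sampler uptake / inversion.** First-order exchange between
  water and polymer: absorbed amount
  `N(T) = ∫ Rs · cw(t) · exp(−ke (T−t)) dt`, with sampling rate
  `Rs = ke · Kpw · m`; for constant `cw`,
  `N = Kpw · m · cw · (1 − exp(−ke T))`, inverted by
  `water_concentration()`. `Kpw` comes from the cosolvent method
  (OLS of log₁₀ Kpw on methanol mole fraction, intercept = pure-water
  value), `ke` from performance-reference-compound dissipation
  (`ke = −ln f / t`). In the kinetic regime the inferred concentration
  scales as 1/assumed-exposure-time, which `scenario_table()` uses to
  report duration scenarios when the true plume contact time is unknown.
* **Tracer dispersal.** Depth-averaged advection–diffusion–decay
  `∂C/∂t + u·∇C = D∇²C − λC` on a regular grid (flux-form upwind +
  centred diffusion; positivity-preserving, mass-conserving), driven by
  synthetic tidal + residual currents and a 7-cage, 12-h-interval release
  schedule. Products: the cellwise maximum-concentration map and the
  accumulated time above threshold.
* **Effects analysis.** Tank-level mortality vs control via a two-sided
  exact test (full hypergeometric enumeration) or a tank-level
  randomization test; the lethal threshold is the lowest dose with
  significant positive excess mortality.

## Worked example

Duration scenarios for four sampler stations (base estimates assume 12 h
of plume contact; each row conserves `cw × t`):

```r
library(plumetox)
base <- data.frame(station = c("B", "C", "D", "E"), depth_band = "3-5 m",
                   cw = c(143, 140, 74, 364), t_ref = 0.5,
                   distance_to_pen = c(45, 105, 120, 15))
scenario_table(base, durations = c(0.5, 1, 2, 3.5))
#> Water concentrations (ng L^-1) by assumed exposure duration (days)
#> (integer-rounded; +/-50% analytical uncertainty)
#>       B   C  D   E
#> 0.5 143 140 74 364
#> 1    72  70 37 182
#> 2    36  35 19  91
#> 3.5  20  20 11  52
```

The lowest estimate (11 ng L⁻¹, station D at 3.5 days of assumed
exposure) is still five times the lethal threshold. The laboratory
effects analysis on synthetic tank data with the study's design:

```r
analyze_exposure(gen_mortality(seed = 42))
#> Exposure effects analysis (vs control, alpha = 0.05 )
#> Dose 0.0008 ng/L: mortality 0% (control 0%), excess +0%, p = 1 [pooled-exact]
#> Dose 0.04 ng/L: mortality 0% (control 0%), excess +0%, p = 1 [pooled-exact]
#> Dose 2 ng/L: mortality 78% (control 0%), excess +78%, p = 3.822e-14 [pooled-exact]
#> Lethal-effect threshold: 2 ng/L
```

A small dispersal run (6 × 6 km, dx = 100 m, two cage releases 12 h
apart, 30 h simulated) and its impact metrics:

```r
grid  <- tracer_grid(60, 60, 100)
flow  <- gen_flow_field(flow_field_spec(seed = 1), duration_h = 32, dt_s = 400)
sched <- build_schedule(2, 12, positions = cbind(1000, 3000))
h <- simulate_dispersal(grid, flow, sched,
                        tracer_params(dt = 400, duration_days = 1.25))
mm <- max_map(h)
area_above(mm, 2, grid$cell_area)            # 3.74 km2 above lethal level
max_extent(mm, 2, grid, c(1000, 3000))       # 3.85 km from the release
max_duration(time_above(h, 2))               # 17 h above 2 ng/L somewhere
```

Even this short two-cage scenario carries lethal concentrations
kilometres past the 500 m regulatory exclusion zone. `plot(h)` draws the
maximum-concentration map with the 2 and 200 ng L⁻¹ contours;
`contour_polygons()` + `write_contours_geojson()` export the exceedance
zones.

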