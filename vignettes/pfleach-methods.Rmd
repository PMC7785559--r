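---
title: "Modelling PFAA leaching and plant uptake with pfleach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling PFAA leaching and plant uptake with pfleach}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfleach)
```

## The problem

Perfluoroalkyl acids (PFAAs) such as PFOA and PFOS are not degraded by soil
microbes, yet field studies consistently recover less substance than was
applied. The accepted explanation is the formation of non-extractable
residues (NER): substance irreversibly bound to the soil matrix, unavailable
to leaching, plant uptake or chemical extraction. A leaching model for PFAAs
therefore needs a sink term that conventional pesticide models express as
biodegradation, reinterpreted as a kinetic, irreversible fixation of the
adsorbed phase.

`pfleach` implements a one-dimensional daily soil-column model of this
system — a free-draining agricultural lysimeter with an annual crop
rotation — together with the calibration machinery needed to confront it
with monthly leachate observations: a multi-target Kling–Gupta objective
and a two-stage behavioural particle-swarm search with uncertainty
envelopes. A synthetic-data module generates everything the corresponding
field experiment measures, so the whole chain is testable end to end with
known "truth" parameters.

## Water

Flow is a capacity ("tipping-bucket") cascade at daily resolution. Each
layer holds water between wilting point and saturation; water above field
capacity drains downward at up to `k_matrix` (mm/d). Rainfall in excess of
the topsoil's matrix infiltration capacity — and any supersaturation left
after the drainage cascade — is routed to a single preferential-flow
(macropore) store that reaches the column bottom with a one-day travel
time. Snow accumulates below 0 °C and melts degree-day (2 mm/°C/d).
Potential evapotranspiration uses the FAO-56 Penman–Monteith form when
radiation, humidity and wind are available (albedo in the radiation term,
the crop's minimum stomatal resistance, divided by the reference active
leaf area 1.44, as surface resistance) and a Hargreaves fallback otherwise.
Canopy cover splits potential ET into soil evaporation and transpiration by
a Beer-law factor `1 − exp(−0.6·LAI)`; transpiration is extracted over the
root zone with an exponential root-density profile.

A Richards-equation or kinematic-wave solution is deliberately out of
scope: the only flow observable in this design is *monthly* percolation,
and daily rainfall forcing already damps the short-term peaks that would
distinguish the more elaborate flow physics. The daily balance
`precip = Δstorage + actual ET + bottom outflow` closes to numerical
precision, which the test suite asserts at 1e-9 mm.

Crop development is static and date-driven (linear LAI and root-depth
development between fixed phenology dates), mirroring the plant-growth
simplicity of established pesticide-leaching models; this is a known source
of error in dry years when actual evapotranspiration is overestimated.

## Substance fate

Within each layer and day, operators run in a fixed order:

1. **Equilibrium sorption.** The reversibly held mass splits between pore
   water and the sorbed phase by a Freundlich isotherm `s = K_f c^n`, with
   `K_f = K_fOC · f_OC` per layer. Units matter for `n ≠ 1`: the solve is
   done in mg/l against mg/kg so that `K_f` in ml/g applies directly, and
   the numeric value of `K_f` is not transferable across unit systems.
   The partition equation `V·c + M_soil·K_f·c^n = M` has no closed form;
   a bracket-safeguarded Newton iteration solves it to 1e-12 relative
   (upper bracket `min(M/V, (M/B)^(1/n))`; masses below 1e-12 mg per layer
   are treated as zero concentration — the nonlinear solve is
   ill-conditioned at denormal scales and the mass is physically
   meaningless).
2. **Scenario kinetics.** Scenario I (reversible two-site): a fraction
   `f_ne` of the sorption capacity is a kinetic pool relaxing toward
   `f_ne·K_f·c^n` at rate `α_k/f_ne`, discretised implicitly over the day;
   the exchanged mass moves to/from the dissolved pool exactly. Scenario II
   (NER): the fraction `1 − exp(−r_NER·Δt)` of the *equilibrium sorbed*
   pool transfers irreversibly to the NER pool — only adsorbed substance is
   fixed, no soil-moisture or temperature modifier, and the NER pool never
   decreases.
3. **Transport.** First-order upwind advection with the matrix percolation
   fluxes plus dispersive/diffusive exchange between adjacent layers with
   `D = D_v·|v| + D_w·τ` (Millington–Quirk tortuosity
   `τ = θ^{7/3}/θ_sat²`, `D_w` default 4.9e-5 m²/d). Sub-daily sub-steps
   cap the advective Courant number at 0.5 (at most 24 sub-steps). Water
   routed through the macropore store picks up the dissolved concentration
   of its source (top) layer and bypasses the matrix entirely.
4. **Plant uptake.** Passive transpiration-stream uptake: per layer
   `f_star · c_soil · transpired volume`, capped at the dissolved mass.
   The Briggs relation `TSCF = 0.784·exp(−(log K_OW − 1.78)²/2.44)` is
   provided as a screening estimate of `f_star`; for PFAAs it is known to
   overestimate calibrated values by orders of magnitude, partly because
   field samples analyse above-ground biomass only.

The applied mass enters the dissolved pool of the top layer on the
application date — a worst-case surface spill; product purity is stored as
metadata but the nominal mass is applied, consistent with balance tables
that use the nominal masses as denominators. Solute mass closes to 1e-6
relative every day (asserted in tests; in practice closure is at machine
precision because every operator is written as an explicit transfer).

Monthly leachate concentration is flux-averaged (leached mass over
percolated volume) for months with outflow. For months without outflow the
pore-water concentration of the lowest layer is reported separately in the
daily output — concentrations without leachate are undefined as
observations and are excluded from concentration scoring.

## Calibration

Per target series `x` (monthly percolation `Q`, monthly concentration
`C` per substance, seasonal uptake `U` per substance),

`KGE_x = 1 − sqrt((r−1)² + (α−1)² + (β−1)²)`,

with Pearson `r`, variability ratio `α = s(m)/s(o)` (sample standard
deviations; at realistic series lengths the population/sample distinction
is immaterial) and bias ratio `β = mean(m)/mean(o)`. `KGE_all` is the
arithmetic mean over the targets. A constant simulated series gets `r = 0`
rather than an error; constant or zero-mean *observations* make the metric
undefined and raise one.

The search is a two-stage behavioural procedure. Stage 1 runs independent
global-best PSO chains (inertia 0.72, cognitive = social = 1.49, reflecting
bounds, every evaluation retained) over the prior ranges; the default
full-scale budget is 15 chains × 32 particles × ≤ 3000 simulations. All
evaluations above the first behavioural threshold (default 0.6) define, by
their per-parameter minima and maxima, the stage-2 search intervals; stage
2 (default 10 chains, ≤ 32 000 each) re-searches that space, and its
evaluations above the second threshold (default 0.75) form the behavioural
ensemble. Pointwise minima/maxima of the ensemble's simulated series give
uncertainty envelopes; per-parameter posterior statistics (min, 5th, 50th,
95th percentile, max) use linear-interpolation (type 7) quantiles. A chain
stops when its best personal best improves by no more than
`sqrt(.Machine$double.xmin)` between iterations — in practice the
simulation cap terminates chains. `f_star` is searched on the log10 scale
(its prior spans three orders of magnitude); all other parameters are
linear. Objective evaluations are memoised by parameter vector, and a
master seed deterministically spawns per-chain seeds, so a run is exactly
reproducible.

## Synthetic data

The weather generator emulates a central-German lowland climate: wet/dry
occurrence from a first-order Markov chain with seasonal persistence,
gamma-distributed wet-day amounts scaled so the expected annual total is
650 mm (with a mean-one lognormal year factor, CV 0.15), a temperature
sinusoid (mean 9 °C, half-amplitude 9 °C, coldest mid-January), and
radiation/humidity/wind consistent with an annual reference ET around
600–700 mm. It does *not* reproduce any actual weather record, spatial
correlation, or multi-day storm structure beyond first-order persistence —
so passing tests demonstrate internal consistency of the method chain, not
agreement with the historical lysimeter record, whose forcing data are not
shipped.

The default crop rotation is the nine-season sequence winter wheat, winter
rye, canola, winter wheat, winter barley, canola, winter wheat, winter
barley, winter rye (harvest years 2007–2015), with genus-typical phenology
dates and a separate stomatal-resistance parameter for canola.

`generate_study()` runs the simulator with known truth parameters and emits
what the experiment measures: monthly percolation, monthly leachate
concentrations (only months with outflow; censored below a 0.1 µg/l
reporting limit) and per-season uptake, each with multiplicative
lognormal, mean-one noise. The default CVs — 0.10 (volumes), 0.20
(concentrations), 0.30 (uptake) — are plausible for monthly composite
sampling and seasonal biomass analytics; no published error model exists
for the original data, so these are package choices, configurable in
`noise_spec()`.

## Scaled experiment designs

Two statistical properties are exercised at desk scale in the test suite;
their designs differ deliberately from the full-scale defaults:

* **Parameter recovery.** A 0.4 m, 4-layer column with uniform
  `f_OC = 0.003` under a wetter (900 mm/yr) climate over 4 years, truth
  `K_fOC` 40 (PFOA) and 300 (PFOS) — all inside the prior ranges — so that
  both substances break through inside the observation window (at the
  full-scale parameters PFOS would not reach 1.5 m for a decade, leaving
  the concentration target unobservable). The PFOA triplet
  (`K_fOC`, `r_NER`, `f_star`) is calibrated with stage budgets
  4 × 8 × 40 and 3 × 6 × 36 and behavioural thresholds 0.15/0.45; the wide,
  many-chain stage 1 is what gives the behavioural set enough coverage for
  a min–max containment check at a few hundred simulations. The thresholds
  are lower than the full-scale 0.6/0.75 because short, noisy seasonal
  uptake series (4 points at CV 0.3) bound the attainable `KGE_all` well
  below what eight years of data support.
* **Scenario discrimination.** Data generated under NER formation
  (scenario II) are fit by both sorption concepts with equal budgets. The
  design uses truth `K_fOC = 150` and a 6-year window so that the
  breakthrough completes and concentrations collapse within the
  observations: this is precisely the signature reversible kinetics cannot
  reproduce. With weak sorption or short windows, a slow kinetic pool
  (`α_k` small) is observationally equivalent to an irreversible sink and
  the two concepts cannot be told apart — the discriminating information
  is the long declining tail, which is also what identified the NER concept
  at full scale.

## Numerical choices and degenerate inputs

* Operator order fixed: water → equilibrium → scenario kinetics →
  transport → uptake.
* Freundlich solve: relative tolerance 1e-12, bracketed Newton; `n = 1` and
  `K_f = 0` short-circuit to the closed form; non-convergence raises an
  error with the residual.
* Transport: explicit sub-steps, Courant ≤ 0.5 and diffusion number ≤ 0.4,
  cap 24 sub-steps/day, then an error (no silent accuracy loss).
* Zero applied mass, zero rates, `f_ne = 0`, `LAI = 0`, zero-rain days and
  empty macropore stores are all exact no-ops of their operators.
* Quantiles: linear interpolation (R type 7), stated for reproducibility.
* Problem sizes in the shipped tests (column depth, years, swarm budgets)
  are the package's scaled study conditions described above.

## Limitations

* No within-plant compartmentation (shoot vs. grain), no volatilisation or
  air–water interface sorption, no competitive sorption at > 1 mg/l, no
  temperature/moisture dependence of NER formation (deliberately switched
  off, matching the study design).
* Plant uptake uses a single, time-invariant `f_star` per substance; crop-
  and season-specific uptake is known to be the dominant unexplained
  variance in field data after the first season.
* The flow engine cannot represent event-scale macropore dynamics driven by
  sub-daily rainfall intensity; monthly percolation is the intended
  resolution.
* Four replicate lysimeters in the motivating experiment are represented by
  a single synthetic column; replicate-to-replicate variability is not
  modelled.
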