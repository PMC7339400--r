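---
title: "Modeling riverbed carbon diagenesis and resuspension with bedcarbon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling riverbed carbon diagenesis and resuspension with bedcarbon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedcarbon)
```

## What the package models

`bedcarbon` simulates the benthic leg of the watershed carbon cycle: the
deposition of particulate organic carbon (POC) onto a riverbed, its
diagenesis (mineralization to methane and carbon dioxide), burial,
resuspension, and the resulting carbon budget of a stream reach fed by
daily upland sediment, POC and dissolved organic carbon (DOC) loads. The
design goal is a *closed* budget: every gram of carbon entering the system
is accounted for by outlet export, burial, inorganic release,
mineralization or a change in storage, to machine precision, every day.

Three coupled components do the work:

1. **Two-layer sediment diagenesis** (`diagenesis_step()` and its pieces).
   A thin aerobic surface layer (`h1`, default 1 mm) sits on a thicker
   anaerobic layer (`h2`, default 10 cm). Settled organic carbon is split
   into labile (G1), slow-reacting (G2) and non-reacting (G3) pools by
   fixed fractions. G1 and G2 mineralize by first-order kinetics with
   Arrhenius-style temperature correction; all three pools are buried at a
   constant burial velocity and resuspended in proportion to bed-sediment
   resuspension. Mineralized carbon, net of an optional denitrification
   sink, becomes dissolved methane; production above a dissolved-transport
   capacity leaves immediately as bubbles. Dissolved methane delivered to
   the aerobic layer is partitioned among diffusion to the water column,
   oxidation to CO~2~ (which leaves as gas) and resuspension.

2. **Single well-mixed reach** (`step_reach()`). Upland loads enter as a
   start-of-day pulse. Suspended sediment exchanges with an erodible bed
   store under a Bagnold-type transport capacity
   `spcon * (prf * velocity)^spexp`: excess settles, deficit resuspends
   (limited by the store), and the resuspended sediment flux drives the
   benthic carbon resuspension above. Labile and refractory POC settle at
   pool-specific velocities and dissolve slowly into DOC; DOC is tagged by
   source (terrestrial vs in-river) and the tags never mix — dissolution
   and algal mortality feed only the autochthonous tag.

3. **Budget accounting** (`annual_budget()`, `ratio_table()`,
   `benthic_budget()`), which normalizes cumulative fluxes by watershed
   area into kgC ha^-1^ yr^-1^ (1 kgC ha^-1^ = 0.1 gC m^-2^) and derives
   the standard diagnostic ratios (outlet/watershed, net
   deposition/watershed, resuspension/deposition, burial quotients) and
   the percentage fate of deposited carbon.

## Parameters that matter

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| `f_g1,f_g2,f_g3` | G-fraction split of settled C | – | 0.65 / 0.20 / 0.15 |
| `k_g1`, `k_g2` | mineralization rates at 20 °C | day^-1^ | 0.035, 0.0018 |
| `theta_g1`, `theta_g2` | temperature bases | – | 1.1, 1.15 |
| `w_bury` | burial velocity | m day^-1^ | 6.85e-6 |
| `rho_sed` | bed sediment density | Mg m^-3^ | 1.6 |
| `v_diff` | CH~4~ diffusion velocity | m day^-1^ | 0.5 |
| `k_ch4_ox` (`theta_ch4_ox`) | CH~4~ oxidation rate | day^-1^ | 100 (1.079) |
| `ch4_sat_ref` (`theta_sat`) | CH~4~ saturation at 20 °C | gC m^-3^ | 37 (1.024) |
| `v_lpoc`, `v_rpoc` | POC settling velocities | m day^-1^ | 0.12, 0.36 |
| `spcon`, `spexp`, `prf` | sediment transport capacity | mixed | 0.003238, 1.1975, 0.022 |
| `er_poc` | POC enrichment ratio of eroded soil | – | 2.98 |
| `k_poc_diss`, `k_doc_min` | water-column rates | day^-1^ | 0.002, 0.005 |

The G-fraction split, mineralization rates and temperature bases are the
standard defaults of the three-G diagenesis framework used by stream
water-quality models; the burial velocity is the conventional low inland
value (three orders of magnitude below coastal defaults, which is why
burial is a percent-level term in the budget). The settling velocities,
enrichment ratio and channel transport coefficients default to values
calibrated for a small Mid-Atlantic coastal-plain watershed; all are
config-overridable (`[diagenesis]`/`[routing]` sections of the flat
key-value config read by `read_run_config()`).

Two closures are deliberate design choices where the governing framework
is under-determined:

* **Bubbling threshold.** The dissolved-transport capacity that caps
  `j_ch4_d` is `v_diff * ch4_sat(T)` with
  `ch4_sat(T) = ch4_sat_ref * theta_sat^(20−T)`. This preserves the
  qualitative behavior — bubbles appear only when diagenesis outruns what
  diffusion can carry at saturation, and colder water holds more methane —
  with a single interpretable constant. At default rates the capacity
  (~18 gC m^-2^ day^-1^) is far above typical diagenesis fluxes
  (~1 gC m^-2^ day^-1^), so bubbling is a storm-free-board term rather
  than a routine pathway; total inorganic release is insensitive to the
  split.
* **Denitrification.** `j_c_den` defaults to zero (nitrogen cycling is out
  of scope). A known nitrate reduction flux can be expressed in carbon
  units via the stoichiometric constant `C_PER_NO3N` (≈1.07 gC per gN,
  from 5 CH~2~O : 4 NO~3~^-^) and passed as a constant sink; it is capped
  at the diagenesis supply.

Resuspended G3 (non-reacting) carbon re-enters the water column in the
refractory POC pool, as does all resuspended bed organic carbon — once
material has been through the bed we treat it as refractory.

## Numerical scheme

* **Anaerobic pools: explicit Euler at dt = 1 day.** The fastest sink
  (`k_g1` = 0.035 day^-1^) gives a stable, accurate daily step, and the
  1-day fixed point coincides with the continuous steady state
  `POC* = J_dep / (k·θ^(T−20)·H₂ + w_bury)` (the suite checks agreement
  within 1%). Sinks are computed from start-of-step state; if their sum
  would overdraw the pool plus the step's deposition they are rescaled
  proportionally so the pool bottoms out at exactly zero — no silent
  negative mass, and per-pool conservation holds to 1e-9 relative.
* **Aerobic methane: implicit (backward) Euler.** With `h1` = 1 mm the
  combined loss rate is ~500 day^-1^, far beyond explicit stability. The
  implicit step is unconditionally stable, nonnegative, exactly
  conservative, and its fixed point equals the closed-form steady state
  `CH₄* = j_d/(v_diff + v_ox + v_res)` at any dt, so the
  diffusion/oxidation flux ratio `v_diff/(k·θ^(T−20)·H₁)` is reproduced
  exactly.
* **Water column: exact linear-reservoir update.** Daily flushing rates
  exceed 1 day^-1^ in this reach, so instead of explicit Euler each pool
  uses the analytic decay `M₁ = (M₀ + L·dt)·e^(−λ·dt)` with the removed
  mass split among outflow, settling and dissolution in proportion to
  their rates. This reproduces the completely-mixed steady state
  `out = in/(1 + v·A/Q)` exactly and can never go negative. Depth varies
  daily; masses (not concentrations) are carried across days so volume
  changes do not create or destroy mass.
* **Sequencing.** Within a day: loads enter, sediment exchanges with the
  bed, the water column advances (producing settling fluxes), then the
  bed advances. Benthic resuspension returns to the water column with a
  one-day lag; the in-transit mass is part of the conservation
  accounting. Resuspension is ~0.4% of deposition at realistic forcing,
  so the lag is immaterial.
* **Degenerate inputs.** Zero flow, zero depth-days, empty pools and
  zero denominators are either handled analytically (λ = 0 branches,
  `NA` ratios) or rejected with informative errors (negative forcing,
  calendar gaps, rank-deficient sensitivity designs).

The budget's `inorganic_release` column counts *all* inorganic carbon
leaving the bed — diffusion, both bubble pathways, and the (tiny)
porewater methane carried out by resuspension — so the accumulated-carbon
residual closes exactly on the sediment storage change. Annual averages
use complete calendar years by default; a `years = "all"` mode divides by
n/365.25 instead, since published multi-year summaries sometimes include
partial years. When the worked ratio table is computed from rounded
published fluxes, the residual of 11.5 − 0.04 − 0.34 − 9.05 is 2.07
kgC ha^-1^ yr^-1^ while the source text quotes 2.02 from its own rounded
inputs; both round to 18% of deposition, and we record the discrepancy
rather than reconcile it.

## The synthetic forcing generator

`generate_forcing()` emulates the statistical structure the analysis
needs, with no external data: Poisson storm arrivals (0.10 day^-1^) with
exponential magnitudes (mean 6 m^3^ s^-1^) and exponential recession
(0.33 day^-1^) over a 1 m^3^ s^-1^ baseflow; at-a-station hydraulic
geometry for velocity and depth; a sinusoidal annual temperature cycle
(15.4 ± 10 °C); a sediment rating curve on the storm component of flow
(so baseflow days carry no erosion); upland POC proportional to eroded
sediment through the topsoil carbon content (1.2%) and enrichment ratio;
and DOC proportional to runoff depth with mean-one lognormal noise. The
default watershed (22,070 ha) and reach (20 km × 30 m) give a water
surface of 0.6 km^2^ — about the scale implied when an areal benthic flux
of ~0.85 gC m^-2^ day^-1^ corresponds to ~9 kgC per watershed hectare per
year. Magnitude constants were chosen once so that a multi-year run
yields upland contributions of roughly 35 kgC ha^-1^ yr^-1^ POC and 45
kgC ha^-1^ yr^-1^ DOC, the regime reported for small mixed-land-use
coastal-plain watersheds.

What the generator does *not* emulate: spatial structure (one reach, no
network routing), snow and frozen-ground seasons, hysteresis in the
sediment rating, land-management schedules, and observation error. A
passing suite therefore demonstrates internal consistency and the
qualitative process hierarchy (settling ≫ resuspension), not predictive
skill on any real watershed — reproducing observed monthly NS/P~bias~
statistics requires the real forcing and a full watershed model, which is
exactly why the tests target conservation laws, closed-form steady states
and orderings instead.

## Evaluation and sensitivity

`nash_sutcliffe()` and `pbias()` implement the two standard monthly
evaluation statistics (`NS = 1 − Σ(O−P)²/Σ(O−Ō)²`;
`P_bias = 100·(Ō−P̄)/Ō`, positive = underestimation), on calendar-month
sums (`aggregate_monthly()`). `run_sensitivity()` re-enacts the global
sensitivity procedure: Latin-hypercube draws over parameter ranges, one
simulation per draw, NS of monthly outlet POC as the objective, then an
OLS regression of the objective on the parameters with two-sided t-tests;
parameters are ranked by p-value. A constant objective returns p = 1 for
every parameter (a constant objective is insensitive to everything by
definition). On the default synthetic run with k = 100 the two settling
velocities rank 1–2 with p < 0.05 and the three channel-sediment
parameters are insignificant, reproducing the expected dominance of
deposition over resuspension. Because the number of runs behind the
published ranking is unknown, the suite asserts the ordering, not the
p-values.

Problem sizes used throughout the suite and acceptance script — 4
simulated years (1461 days) for budgets and sensitivity, 2 years for
parameter recovery, k = 100 hypercube runs, 5 × 5 recovery grids — were
chosen as the smallest sizes at which the multi-year budget regime,
monthly statistics and rank separation are stable.

## Known limitations

* One reach, vertically and longitudinally lumped; no network, floodplain
  or reservoir processes.
* No dissolved-oxygen or nutrient feedback: sediment oxygen demand can be
  reported via the `O2_PER_C` constant but does not alter kinetics.
* The water column has no methane state: benthic CH~4~ releases are
  reported as fluxes, not tracked to outgassing.
* Algal dynamics are reduced to optional constant debris-settling and
  DOC-mortality source terms.
* Burial-velocity uncertainty spans orders of magnitude in the
  literature; buried-carbon estimates inherit it entirely.
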