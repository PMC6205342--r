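---
title: "The population-based fugacity model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The population-based fugacity model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fugapop)
```

`fugapop` implements a multimedia fugacity model in which every species of
an aquatic food web is its own well-mixed compartment, sized by its
population volume. This vignette explains the model and its assumptions, the
parameters that matter, the numerical choices, and what the built-in
synthetic scenario does and does not emulate.

## Model structure and assumptions

Each compartment holds mass `M = V Z f`. The dynamic equation integrated by
the engine is the full product rule,

$$\frac{df_i}{dt} = \frac{1}{Z_i V_i}\frac{dM_i}{dt}
  - \frac{f_i}{Z_i}\frac{dZ_i}{dt}
  - \frac{f_i}{V_i}\frac{dV_i}{dt},$$

so three separate modules feed the state derivative: the transport mass
balance, the temperature dependence of the fugacity capacities, and the
population dynamics. The standing assumptions are:

1. every compartment is homogeneous — no spatial gradients, no spreading
   delay;
2. population sizes change only through growth, natural mortality and
   predation;
3. lipid fractions are constant per species (so `dZ_B/dt` carries no
   `dL/dt` term);
4. no congener interconversion (dechlorination) and no migration in or out
   of the web.

Assumption 1 also fixes the interpretation of suspended solids: water and
particles share one fugacity, so the dissolved/particulate split is set
entirely by capacities.

## Fugacity capacities

Gas: `Z_gas = 1/(R T_A)`. Aerosol: `Z_aer = 0.1 Z_gas K_OA`, with
`log10 K_OA = a/T_A + b`; the 0.1 factor is kept as the named constant
`aerosol_z_factor` so it is visible and overridable. Water: `Z_wat = 1/H`,
with the van't Hoff correction
`H(T) = H_ref exp(−(ΔU_AW/R)(1/T − 1/T_ref))`. Sorbing solids:
`Z = Z_wat ρ δ K_OC / 1000` with densities in kg m⁻³ and `K_OC` in
L kg⁻¹. Biota: `Z_B = L Z_wat K_OW`.

Two deliberate choices here:

* **K_OC is always computed as 0.41 K_OW**, never user-entered. The
  suspended-sediment volume fraction can be derived from a 70 %/30 %
  dissolved/particulate loading allocation as
  `τ₂ = 3000/(7 ρ₅ δ₅ K_OC)`; with `K_OC` derived, the algebra cancels
  exactly and the dissolved share is 0.70 to machine precision regardless
  of the parameters (this is tested for 1000 random draws).
* **K_OW is temperature-independent by default.** Its internal-energy
  change `du_ow` is stored on the congener and `kow_at(...,
  temperature_correction = TRUE)` enables the analogous van't Hoff
  correction, but nothing in the engine uses it unless asked: the
  octanol–water partition is far less temperature-sensitive than the
  air–water one, and a constant K_OW keeps the τ₂ cancellation exact.

### Analytic capacity derivatives

`dz_dt()` returns the exact derivatives of the bulk capacities along the
forcing temperature trajectory. They are the symbolic derivatives of the
implemented capacities — for air this includes the chain-rule factor
`−a ln(10) 10^{a/T+b}/T²` from K_OA(T), and for water/sediment/biota the
factor `−ΔU_AW/(H R T_W²)` from 1/H(T). Each derivative is verified against
a central finite difference on a 273–303 K grid to a relative tolerance of
1e-6; that agreement, not any printed formula, is the contract. Sediment
and biota deliberately share the water temperature.

## Transport: the D-value ledger

Every transport or transformation process is one directed record
`(source, sink, coefficient)` with flux `D·f(source)`; boundary records are
`input` (driven by an inflow fugacity) or `exit`. This "ledger" design means
closure is structural: summing `dM/dt` over compartments of a system with no
boundary records gives zero identically, and the engine's audit confirms it
numerically.

Readings adopted where the rate-law typography was ambiguous:

* dry aerosol deposition `D = A_AW v_Q Z_aer` and wet scavenging
  `D = A_AW U_R U_Q Z_aer`: each must be area × velocity × capacity to be
  dimensionally consistent, so the rain rate `U_Q` multiplies only the
  scavenging term and the two velocities are independent configuration
  fields. Because these records carry the full aerosol-phase capacity, the
  velocity and scavenging ratio must be understood as aerosol-volumetric
  (the physical particle velocity times the ~1e-11 aerosol volume
  fraction); the toy-lake generator parameterises them accordingly.
* the feeding kernel is `0.022 e^{0.06T} W_B^{−0.15}` in kg food per kg
  predator per day — the gross ration `G_D = 0.022 W_B^{0.85} e^{0.06T}`
  divided by body mass.
* the dietary three-way split uses the grouping
  retained `= E_D (TMF^{ΔTL} − 1)/TMF^{ΔTL}`,
  gut–feces `= E_D TMF^{−ΔTL}`, undigested `= 1 − E_D`: the three sum to
  one for any `E_D ∈ [0,1]`, `TMF > 0`, so ingestion conserves chemical,
  and TMF = 1 yields zero net magnification. A non-positive trophic-level
  difference (mutual predation) is clamped to 1e-6 with a warning rather
  than crashing on realistic webs. TMF < 1 (trophic dilution) is allowed;
  it makes the retained share negative, i.e. a net fugacity sink for the
  predator.
* dietary records follow the printed form
  `feed·ρ_i·V_{P,i}·p_{ij}·Z_{B,j}` without a division by prey density;
  this assumes organism densities are close to one another (all are near
  water density), and the same convention on every branch of the split
  keeps the partition conservative. The *population* predation loss, by
  contrast, converts predator ration to prey volume by dividing by the
  prey density, because the population balance is a volume balance.
* egestion and mortality fluxes are routed to the **sediment** by default,
  following the final composite balances; a configurable
  `mortality_to_water` fraction reroutes part of the pelagic mortality flux
  to the water column for users who prefer the narrative routing. Burial is
  off (`burial_flow = 0`) by default and adds a sediment exit when enabled.
* benthic species respire pore water: their gill records exchange with the
  sediment fugacity but carry the pure-water capacity.

## Population module

Rates (per day): growth `0.00586·1.113^{T−20}·(1000 W_B)^{−0.2}`, natural
mortality `4.899 t_max^{−0.916}` per year divided by 365, and the feeding
kernel above. The mortality law's published form carries a composite
`1/365000` factor; the package decomposes it as year→day conversion
(`1/365`) times a per-mille mass-bookkeeping factor that is kept as the
named constant `mortality_mass_scale = 1e-3` and applied only to the
*chemical* mortality D-value. The population balance uses the plain
`day⁻¹` rate: that is the only reading under which a food web with
realistic maximum ages is feasible (mortality below growth) and the
annualized coefficient at `t_max = 1` is exactly 4.899 yr⁻¹.

`balance_populations()` solves the steady-population closure
growth = mortality + predation as one linear system: one equation per
preyed-upon species, one unknown per consumer. For chain-like webs with a
single producer and a single apex predator the system is square; branched
webs are solved in the least-squares sense and the residuals reported.
Apex species contribute no equation — their imbalance `(k_G − M)V_P` is
reported, never silently zeroed. The toy-lake generator chooses the apex
maximum age from the growth/mortality identity at the reference
temperature, which keeps that residual below 1 % of the growth term.

Producer standing stock uses the energy–mass route: daily areal solar
energy × photosynthetic efficiency × coverage × transport factor × carbon
yield × area × lifetime, divided by the carbon mass fraction (the carbon →
biomass conversion divides, it does not multiply — the carbon fraction is
the weight share of carbon in the organism). The seconds→day factor 86400
is explicit.

## Engine and numerics

* **Steady state** freezes temperatures and populations and solves the
  linear system `A f = −b` directly (`solve()`), with a relative-residual
  check at 1e-10. A compartment with no loss pathway makes the system
  structurally singular and is reported by name. Negative solutions flag a
  nonphysical parameter set.
* **Dynamics** use `deSolve::lsoda` (stiffness-switching) with defaults
  `rtol = 1e-8`, `atol = 1e-12` Pa — fugacities span many orders of
  magnitude, so the absolute floor matters. Because the forcing is
  piecewise linear, its slope is discontinuous at breakpoints;
  `fug_simulate()` therefore integrates segment-by-segment between
  breakpoints so the right-hand side is smooth inside every solver call
  (temperature slopes are taken exactly from the segment slopes, never by
  numerical differentiation).
* **Initial conditions** must be supplied; the default is the steady state
  at `t = 0`, and `"zero"` is available for spin-up studies.
* **State ordering** is fixed: air, water, sediment, then species in
  declaration order.
* **Population dynamics are off by default** (constant populations); when
  on, the population volumes join the state vector and the growth-dilution
  term of the product rule becomes active.
* The **mass-balance audit** integrates the per-compartment gain/loss
  series on the output grid (trapezoidal rule) against the storage change.
  For steady or closed systems the closure is exact up to solver
  tolerance; for strongly transient runs the audit's quadrature error is
  controlled by the output grid density, not by the integrator.

## The toy-lake scenario

`make_toy_lake()` emulates a small temperate lake: ~10 km² surface, ~10 m
water column, a 0.1 m bio-active sediment layer with 10 % dry residual, a
PCB-153-like congener (log K_OW 6.5–7.1, TMF 1.6–2.6, reaction lifetimes of
order 10²–10⁴ days), seasonal or constant temperature forcing, a 0.5 mol
day⁻¹ water-column load, and a 3–8 species web from phytoplankton to a
predatory fish with a benthic branch. All randomisation is a seeded jitter
around those anchors, so a seed fully determines the scenario; infeasible
draws (negative populations, producer density outside the observed
0.01–1 g m⁻³ phytoplankton range) are re-drawn a bounded number of times.
Problem sizes used in the shipped tests — a 10-year closed seasonal run for
conservation, 20 random scenarios for the steady/dynamic comparison, 1000
draws for the partition identities — were chosen as the smallest sizes at
which the properties are meaningfully exercised.

What the toy lake does **not** emulate: spatial structure (one box per
medium), congener mixtures, seasonal lipid dynamics, stage-structured or
stochastic demography, fishery removals, and any calibrated real-lake
parameter set. Passing tests on the toy lake therefore demonstrate the
internal consistency of the model — conservation, equipartition,
steady/dynamic agreement, closure identities — not predictive skill for a
specific lake, which requires site-specific inputs.

## Known limitations

* The dietary D-value convention (no prey-density division) makes dietary
  uptake dominate gill uptake more strongly than field
  biomagnification-factor compilations suggest; fugacity ratios along the
  chain should be read qualitatively.
* The steady-population closure is exact only below the apex; apex species
  are diagnosed, not closed.
* Inflow fugacities and emissions are exogenous time series; there is no
  watershed or atmospheric sub-model.
* Uncertainty propagation (Monte-Carlo over congener properties) is out of
  scope, though the seeded generator provides a clean seam for it.
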