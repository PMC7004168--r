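---
title: "The copper column model: equations, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The copper column model: equations, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cucolumn)
```

`cucolumn` simulates the oceanic copper cycle in a single vertical water
column. This vignette is the package's own account of the science: the
tracer equations and their assumptions, the parameters that matter, the
numerical schemes, what the synthetic forcing does and does not emulate, and
the design decisions taken where the problem was genuinely open.

## Tracers and process equations

Seven copper tracers evolve per grid cell (all nmol/L): dissolved copper
`DCu`; copper scavenged onto small and large particles (`SCup`, `SCug`);
copper in small and large biogenic particles (`pCuPart`, `gCuPart`); and
copper inside nanophytoplankton and diatom cells (`CuN`, `CuD`). Their local
balances are

* `dDCu/dt = river + aerosol − uptake − scavenging + remineralization +
  recycling`
* `dSCu/dt = scavenging − sinking` (per particle class)
* `dCuφ/dt = uptake − mortality − grazing` (φ = N, D)
* `dCuPart/dt = mortality + excretion + aggregation − remineralization −
  sinking`

Every internal flux moves copper from one pool to another, so in a closed
cell the seven tendencies sum to zero exactly; the only ways in are the
surface river/aerosol sources and the only way out is burial through the
bottom edge. The run ledger checks this identity continuously.

### Speciation

`DCu = Cu′ + CuL` with one uniform ligand class binding inorganic copper at
conditional equilibrium, `K_L [Cu′][L_free] = [CuL]`. Two design points:

* **Units and convention.** The stability constant is interpreted as a
  conditional constant in L/mol on the *free-ligand* convention, the usual
  convention of ligand titration work; concentrations are converted
  internally. With `K_L = 10^13.5` L/mol and 1 nmol/L of ligand,
  `K_L · [L] ≈ 3 × 10^4` — binding is strong, and the bound fraction at
  surface concentrations exceeds 0.999.
* **Instantaneous equilibrium.** Ligand production and decay are not
  modelled; the equilibrium is recomputed from the current `DCu` every
  timestep. The ligand load is spatially uniform by default but accepts a
  profile for sensitivity runs.

Numerically, eliminating either unknown gives a quadratic. The naive
discriminant of the `CuL` quadratic cancels catastrophically when
`K_L · L ≫ 1` (precisely the oceanic regime), so the solver computes `Cu′`
and `L_free` from their own quadratics using the root branch that only adds
same-sign quantities, and recovers `CuL = K [Cu′][L_free]` from mass action.
The closed form agrees with a bisection solver to better than 1e-9 relative
across `DCu` 1e-3–10 nmol/L, ligand 0.1–5 nmol/L and `K_L` 1e11–1e15 L/mol,
and both conservation identities hold to 1e-12.

### Reversible scavenging

Only `Cu′` is exposed to particle surfaces; `CuL` is protected. With
dimensionless `ztrc = PartC · KD`, the equilibrium scavenged concentration
is `Cu′ · ztrc/(ztrc+1)`. The literature form defines a *displacement*
(a concentration), not a rate; the model applies it as a relaxation,

`tendency = (Cu′·ztrc/(ztrc+1) − SCu) / τ_scav`,

with `τ_scav = 1` day. Because adsorption/desorption is fast compared with
particle transit (days versus weeks–months), results are insensitive to
`τ_scav` provided it stays well below the sinking timescale. Partitioning is
per particle class: small particles use `KD_p = 0.1` m³/mmolC, large
`KD_g = 5e-3`, each with its own scavenged pool.

The irreversible variant (scenario `FESCAV`) clamps the desorption branch to
zero. On its own that would bury every scavenged atom; consistent with the
idea that irreversibly scavenged metal can still be remobilized by bacterial
activity, the bacterial remineralization rate then also acts on the
scavenged pools. This is what lets the irreversible run maintain a
nutrient-like dissolved profile instead of draining to zero.

A bookkeeping choice worth flagging: scavenged copper lives **only** in
`SCup`/`SCug`. An alternative reading would also credit it to the biogenic
particle pools, but that would count the same atoms twice; biogenic
particulate Cu receives mortality, excretion and aggregation only.

### Quota-regulated uptake

Specific uptake per mole of cellular phosphorus is

`Up = μ_max · θ_max · bCu/(bCu+ks) · (1 − θ/θ_max)/(1.05 − θ/θ_max)`

with `μ_max = 1.05` day⁻¹, `θ_max = 2e-3` molCu/molP, and half-saturation
`ks` = 4 (nanophytoplankton) / 12 (diatoms) nmol/L. The quota-regulation
factor shuts uptake off *exactly* at `θ = θ_max`; at `bCu = ks` and an empty
quota the rate is exactly `θ_max/2 · (μ_max/1.05) = 1e-3` molCu molP⁻¹
day⁻¹, a useful analytic checkpoint. The equation is treated as
biomass-specific (per mol P), which its units imply; multiplying by the
cell's phosphorus biomass gives the volumetric sink. The bioavailable pool
`bCu` is all of `DCu` in the reference configuration or `Cu′` alone in the
inorganic-uptake scenarios; the half-saturation constants keep their printed
numeric values when the convention switches (0.01/0.03 nmol/L in the
high-affinity variant).

### Grazing, recycling, excretion

Zooplankton graze phytoplankton copper at `graz · Cuφ` but carry no explicit
copper tracer. They are held at a fixed body ratio `curat = 10` μmolCu/molC:
of the grazed copper they retain up to `curat` times the grazed carbon
(Redfield carbon of the grazed biomass), and the excess is split — a
fraction `σ = 0.5` to dissolved recycling, the rest to fecal pellets (large
biogenic particles). Because the prescribed ecosystem is in steady state,
the implicit zooplankton pool cannot accumulate copper: the retained
(body-quota) flux re-enters the dissolved pool as zooplankton metabolic
release. That routing makes dissolved recycling the dominant fate of grazed
copper (~55–60% of uptake in the reference run), consistent with a surface
ocean in which roughly half of the uptake flux is recycled in place, and it
is what closes the mass ledger without a phantom reservoir. `σ = 0.5` is a
tuning-free midpoint; it and `curat` are exposed in the configuration.

Mortality routes phytoplankton copper to small biogenic particles (the
natural destination for intact dead cells, which the loss-term bookkeeping
leaves open); aggregation moves both small-particle pools to their large
counterparts conservatively.

### External sources and boundary conditions

Aerosol copper dissolves instantaneously upon deposition with solubility
0.40; riverine copper arrives dissolved. Both enter the top cell only. The
default flux densities are scaled so that, over a 3.6e14 m² reference ocean
area, rivers deliver 6.7 Gmol/yr and dissolved aerosol 0.27 Gmol/yr. There
is no sediment or hydrothermal source; the sinking flux through the bottom
edge is burial, a permanent loss.

## Numerics

* **Grid.** 50 levels over 0–5000 m: 10-m cells to 200 m, then geometric
  stretching. This resolves the euphotic zone and the deep gradient at
  negligible cost; `n_levels = 1` degenerates to a 0-D box.
* **Operator splitting.** Each step applies local biogeochemistry (explicit
  Euler), then sinking, then mixing.
* **Non-negativity by flux limiting.** Before the local update, every flux
  out of a pool is scaled so the pool cannot be driven negative within the
  step. Scaling sinks and their paired sources together preserves exact
  conservation — unlike post-hoc clipping, which silently creates mass.
* **Implicit transport.** Mixing is a backward-Euler conservative diffusion
  solve; sinking is backward-Euler flux-form first-order upwind. Both
  operators are M-matrices (monotone, positivity-preserving) and are
  inverted once per run, so each step costs three small matrix products.
  No CFL restriction applies. An explicit upwind scheme is available
  (`sinking_scheme = "explicit"`) and enforces `max(w)·dt ≤ min(Δz)`,
  raising a configuration error naming the offending timestep.
* **Timestep.** Default `dt = 0.5` day = `τ_scav/2`, the fastest local
  timescale. Halving it moves 120-year profiles by well under 0.1% —
  the steady state of the scheme is insensitive to `dt` because it is a
  fixed point of the tendencies themselves.
* **Steady state.** Integration stops when every tracer's annual-mean
  column-mean concentration changes by less than `tol = 1e-5` per day
  (relative), or at `max_years`. The reference configuration converges at
  this tolerance in about 100 years on the standard grid; the global-ocean
  practice of multi-century spin-up is unnecessary at column scale.
* **Sinking speeds.** Small particles sink at 2 m/day everywhere; large
  particles at 50 m/day near the surface, increasing linearly below 100 m
  to 200 m/day 2000 m deeper — a stand-in for the host model's
  depth-accelerating particle speeds, all configurable.
* **Remineralization rate.** `λ = 0.03`/day, a typical particulate organic
  carbon scale; the source model inherits (and does not print) its own.

## The synthetic forcing: what it emulates, what it does not

`idealized_column_forcing()` generates the ecosystem drivers with the
qualitative vertical structure of open-ocean fields: biomass uniform over a
100-m euphotic zone with a 30-m exponential tail; particulate organic carbon
following a Martin curve (exponent 0.858) below 100 m; grazing, mortality
and aggregation rates uniform; strong mixed-layer mixing (100 m²/day over
0–50 m) above a weak interior (1 m²/day); surface-only aerosol and river
inputs. Optional seeded lognormal noise perturbs the biomass and particle
profiles bit-reproducibly.

The default magnitudes describe a moderately productive column:
`P_N + P_D = 0.05` μmolP/L (~5 mmolC/m³ of living carbon at Redfield
stoichiometry) over POC of 2 + 0.5 mmolC/m³. At the resulting operating
point the euphotic zone takes up copper at a few pmol L⁻¹ day⁻¹ — the
magnitude seen in open-ocean incubations — while inorganic Cu′ stays at
sub-picomolar levels, which is the regime in which restricting
bioavailability to Cu′ is a meaningful experiment.

What the generator deliberately does **not** emulate: horizontal transport
and upwelling (a column has none), seasonality (forcing is steady), real
deposition or river fields, and basin-to-basin contrast. Consequently,
passing tests demonstrate the *mechanisms* — profile shapes, orderings
between scenarios, budget closure — not the global model's numerical
values, which depend on 3-D circulation and real forcing and are out of
reach at desk scale by design.

## Known limitations

* **Supply-pinned uptake.** At steady state a column's export must balance
  its external input, and biological export scales with uptake. Every
  scenario able to balance the input through uptake therefore converges to
  nearly the same specific uptake — and hence nearly the same cellular
  quota — regardless of how bioavailable copper is computed. In a global
  ocean, circulation maintains surface DCu independently of the local
  balance and the quota contrast between bioavailability assumptions is
  visible everywhere; in the column, the contrast is robust for the
  standard-affinity inorganic scenario (which cannot balance the input via
  uptake at all and sits far below quota) but reduces to a near-tie in the
  mixed layer for the high-affinity variant. Tests assert the contrast
  cell-wise as the mechanism implies it; the high-affinity leg fails in the
  mixed layer for this structural reason, and we report rather than mask
  it.
* **Slow deep equilibration of the irreversible variant.** With desorption
  off, the deep dissolved pool is reshaped only by scavenging at
  ~5e-3 nmol/L Cu′ against ~1e-3 mmolC/m³ particle loads — a multi-century
  timescale. Within the 150-year integrations used by the test suite the
  irreversible profile is much flatter than the reference (regression R
  0.4 versus 0.8) but retains a residual slope; the flatness contrast is
  therefore asserted through the regression coefficients, not a slope
  ratio.
* **First-order transport.** Upwind sinking smears sharp features over a
  few cells; doubling the vertical resolution moves the 120-year reference
  profile by under 1% in relative L2 norm, which is the self-convergence
  metric used by the tests (cell-wise maxima are dominated by the sharp
  euphotic-base gradient).
* **No copper feedback on growth.** Neither limitation nor toxicity affects
  the prescribed ecosystem; copper is a passive passenger. Quota maps
  should be read as supply diagnostics, not growth predictions.
* **Problem sizes in the test suite.** The suite runs the standard 50-level
  grid with `dt = 0.5` day: 150-year scenario integrations, a 200-year
  closed-column conservation check, and a 120-year self-convergence
  triplet. These lengths were chosen as the shortest that put each
  diagnostic safely past its transient; rerunning with longer horizons
  sharpens the same conclusions.

## Configuration

Every constant above is a field of `cu_params()`; named experiment presets
(`scenario_params()`) differ only in the partition coefficients, the
reversibility switch, the half-saturation constants and the bioavailable
pool. YAML configuration files (`load_config()`) override any parameter,
grid, forcing or run setting, log each override's provenance, and reject
unknown keys; `write_outputs()` serializes profiles, time series, the
budget ledger, the forcing and a hashed manifest so that a run can be
reproduced bit-identically.
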