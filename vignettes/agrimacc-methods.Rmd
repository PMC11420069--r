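---
title: "Methods: agricultural carbon sequestration options, adoption and MACCs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agricultural carbon sequestration options, adoption and MACCs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrimacc)
```

`agrimacc` is a desk-scale re-creation of how economic land-use models
represent CO₂ sequestration options on agricultural land. Everything runs on
a synthetic world, so every mechanism is testable end to end without
downloads. This vignette documents the model equations, the parameters that
matter, the choices made where the design was genuinely open, and what the
synthetic setting can and cannot demonstrate.

## The synthetic world

`generate_world()` draws `n_regions` regions (default 10) assigned to five
groups (AFR, LAM, ASIA, NORTH, OTHER_SOUTH) that govern yield co-benefits and
cost scaling. Global cropland and pasture totals are split across regions by
a Dirichlet allocation (concentration 3 by default, giving realistic
heterogeneity while conserving totals to 10⁻⁶ relative). The default totals
— about 1,698 Mha of cropland and 1,833 Mha of managed grassland — are
back-derived from published adoption shares (900 Mha ≈ 53 % of cropland,
1,100 Mha ≈ 60 % of grassland) and are illustrative, not measured.

Monthly climate follows three latitude-band archetypes (tropical, temperate,
boreal) with additive noise; ordering `t_min ≤ t_mean ≤ t_max`, non-negative
precipitation/radiation and `frost_days ≤ days in month` hold by
construction. Soils carry maximum available soil water, a fertility rating
in [0, 1], and C and N stocks. Per-region SOC and biochar sequestration
coefficients are drawn uniformly inside configured ranges whose defaults
(0.4–0.8 and 1.7–2.5 tCO₂e ha⁻¹ yr⁻¹) sit in the magnitude band reported for
these options' per-hectare efficiency; silvo-pasture coefficients are not
drawn but computed by the growth simulator. One crop and one livestock
aggregate per region suffice because the accounting and adoption mathematics
are commodity-count invariant.

All draws flow from a single root seed; identical configurations serialize
byte-identically (`write_world()` emits 17-significant-digit CSV, so
`read_world()` round-trips exactly).

What the generator does *not* emulate: real geography, spatial
autocorrelation, commodity detail, inter-regional trade, or any price
feedback on demand. Passing tests therefore demonstrate the correctness of
the mechanisms — saturation accounting, calibration, competition, transfer
identities — not the realism of any particular magnitude.

## Silvo-pasture growth

Tree strips (25 % of the silvo-pasture hectare) are simulated monthly:

* light interception: `f = 1 − exp(−k·LAI)` with LAI from foliage carbon and
  specific leaf area; APAR takes half of shortwave radiation as PAR;
* `GPP = α · APAR · ∏ modifiers`, `NPP = y · GPP` with `y = 0.47`;
* modifiers (each clamped to [0, 1]): temperature (skewed optimum form, 1 at
  `t_opt`, 0 at the cardinal limits), VPD (`exp(−k_D·D)`), soil water (bucket
  ratio: the bucket gains precipitation and loses a radiation-proportional
  evaporative demand, coefficient 0.08 mm per MJ m⁻² d⁻¹ day), frost
  (`1 − frost_days/days`), fertility (set to 1 — strips are assumed
  fertilized), age (`1/(1 + (age/0.95·max_age)⁴)`) and CO₂ (1 under
  historical climate);
* allocation: the root fraction falls linearly from 0.6 to 0.2 as the product
  of modifiers rises (harsher conditions push carbon below ground); the
  remainder splits 35:65 foliage:stem; fractions sum to 1 exactly;
* turnover: fixed monthly fractions (foliage ≈ 0.03, roots 0.015, stem 0);
  mortality is ignored over these short rotations. The carbon balance
  `Δpools + turnover = NPP` closes to 10⁻⁹ relative by construction and is
  property-tested.

Species archetypes: a eucalypt, and poplar wherever mean annual temperature
is below 11 °C. Planting densities are fixed per system and species inside
the stated windows: 1,400 (eucalypt) / 2,300 (poplar) stems ha⁻¹ for the
10-year bioenergy rotation (window 1,250–2,500, denser for poplar) and
450 / 580 for the 30-year carbon rotation (window 400–600). The quantum
efficiencies (1.5 × 10⁻⁶ and 1.45 × 10⁻⁶ tC MJ⁻¹) were chosen once so that
annualized strip sequestration lands in the 0.5–2.1 tCO₂e ha⁻¹ yr⁻¹
efficiency band; they are archetype knobs, not species measurements.

Nutrient demand nets compartment increments times tissue N concentrations
against a mineralized soil supply (1 % of the soil N stock per year, a
documented knob replacing a full soil decomposition model); phosphorus is a
fixed 0.1 fraction of nitrogen demand. The annualized sequestration of a
rotation is `0.25 · ΔC · (44/12) / T` on the full hectare, with ΔC the tree
carbon gain including roots over the rotation of `T` years (10 or 30).

## Options, saturation and vintages

Each region's catalog holds five variants: `soc_crop` (cap 90 % of cropland,
saturation 20 yr), `soc_pasture` (60 %, 20 yr), `silvo_bioenergy` (10 yr
biomass equilibrium), `silvo_carbon` (30 yr), jointly capped at 50 % of
pasture and mutually exclusive per hectare, and `biochar` (30 yr), which
carries no area cap because its adoption is feedstock-limited — the reported
~28 % cropland coverage elsewhere is an outcome, not a constraint. Adoption
enters a vintage ledger; a cohort's flux is constant until its horizon and
zero afterwards, so the cumulative stock telescopes exactly
(`area · q · min(T − t₀ + 1, T_sat)`; the adoption year counts as the first
sequestering year — a bookkeeping convention, property-tested for
consistency between `annual_flux()` and `cumulative_stock()`).

Yield co-benefits are linear: 1.5 / 1.2 / 0.7 % yield per tCO₂ ha⁻¹ yr⁻¹ in
AFR / LAM / ASIA, zero elsewhere. The grazing penalty is 25 % of pasture
yield on converted silvo hectares, with no offsetting productivity gain.

## Biochar and the feedstock market

The chain multiplies 0.45 tC tdm⁻¹ carbon content × 0.50 retention × 0.796
100-year storage = 0.17910 tCe tdm⁻¹ (0.18 at the two-decimal display
precision; full precision is used internally). Pyrolysis costs
35 USD₂₀₀₀ tCO₂e⁻¹ and returns half the feedstock as bioenergy byproduct.
Sustainable residue potential is 50 % of production × residue-product ratio;
recovery costs scale with GDP per capita. Wood volumes convert at
0.5 tdm m⁻³ where needed. The baseline residue commitment to existing
bioenergy (~16 EJ yr⁻¹ at 18 GJ tdm⁻¹ ≈ 890 Mtdm) and the forestry-side pool
sizes are configuration knobs scaled with world size.

Allocation is merit order: uses are served in priority order livestock →
exogenous bioenergy → biochar, always from the cheapest pool with remaining
supply; the shadow price is the unit cost of the marginal pool; excess demand
is reported as a shortfall, never an exception. Serving biochar last makes
the competition monotonicity — more bioenergy demand never means more
biochar — structural. The byproduct credit (half of biochar feedstock
offsets bioenergy demand) is resolved by a short fixed-point loop (6
iterations; the map is monotone and contracts quickly).

## Adoption, calibration and MACCs

The GHG price ramps linearly from 0 in 2030 to the endpoint in 2050 (the
ramp's 2030 value is a convention — the start year defines where pricing
begins, not a positive price) and continues linearly if an extended horizon
is evaluated. Adoption is myopic: each 5-year period optimizes against the
current price; together with saturation this generates the early-uptake
effect at high prices. The quadratic cost `C(a) = c₁a + (s/2)a²` has `c₁ = 0`
for SOC options (a slope-only calibration is then exactly determined) and
positive intercepts for silvo systems, whose 30-year variant costs 8 % of the
bioenergy variant's level, reflecting no-harvest, low-density management.
Biochar's per-hectare quadratic slope (200 USD ha⁻¹ per unit share)
represents application and logistics heterogeneity; its carbon cost runs
through the 35 USD tCO₂e⁻¹ pyrolysis charge and the feedstock shadow price.

Calibration: `s = (p·q + v − c₁)/a_target` at `p = 100 USD₂₀₀₀`, targets
90 % (cropland SOC) and 60 % (pasture SOC), with the co-benefit value `v`
held identical between calibration and re-solve, so the round-trip is exact
to floating precision. `v` values the yield gain at the regional crop price,
accumulated over the saturation horizon and annualized (mean cumulated gain
of `(T+1)/2` years).

Ties between options with equal marginal returns are broken lexicographically
by option id (determinism); in practice the binding interactions are the
shared silvo cap, which is filled in id order against remaining headroom.
`build_macc()` reruns the horizon per endpoint from a shared base model (same
world, rotations and calibration; fresh ledger), so duplicate endpoints are
bit-identical.

## Economics

Turnover change is implemented as the revenue difference
`Σ (p_scn·q_scn − p_base·q_base)` — the reading that reproduces the sign
structure of published net figures — with quantities responding to the
non-CO₂ tax through a constant-elasticity contraction (elasticity 0.5, a
reduced form standing in for a full market equilibrium; its magnitudes are
not load-bearing). Tax = emissions × price; subsidy = removals × price;
`net_producer = turnover − tax + subsidy`; `net_government = tax − subsidy`;
transfer neutrality holds identically. Currency converts at 1.63
USD₂₀₀₀→USD₂₀₂₂; price labels floor to the nearest 5 (163 → "160",
326 → "325"), matching conventional reporting granularity. GWPs are AR4: 298
(N₂O) and 25 (CH₄). The MACC-area cost of realized adoption integrates
`c₁ + s·a` exactly (the quadratic antiderivative, so no trapezoid error).

## Scenarios and sensitivity

Five scenario rows are runnable: `baseline` (nothing priced), `default` /
`default_bio` (non-CO₂ only), `agCO2` / `agCO2_bio` (CO₂ removals also
subsidised), `_bio` marking 1.5 °C-compatible bioenergy demand. A FOLU flag
is accepted but inert — forestry responses are out of scope. The sensitivity
suite applies pure transforms: ±10 saturation years (SOC and silvo), doubled
adoption costs, a 30 % livestock demand cut in NORTH regions (the published
description gives no percentage; 30 % is a documented knob), 1.5 °C
bioenergy, tree strips at 20 %/15 % (silvo coefficients scale
proportionally), and caps at 75 %/50 % of default.

## Numerical choices and degenerate inputs

* Stands initialise at 5 × 10⁻⁴ tC per seedling; zero-radiation months yield
  zero GPP and turnover-only dynamics; negative radiation is an input error.
* `optimal_adoption()` handles `s = 0` as a corner (cap if net marginal
  revenue is positive), not a division error; shares outside [0, 1] are
  errors.
* Calibration against a non-positive net marginal revenue raises an explicit
  infeasibility error.
* Infeasible feedstock demand produces a reported shortfall; parse errors on
  world tables name file, row and column.
* Tolerances asserted in the test suite: carbon balance 10⁻⁹ relative,
  closed-form cumulative NPP 10⁻⁶, calibration round-trips 10⁻⁶, slope
  recovery 10⁻⁶ relative, grid-oracle agreement at the 10⁻⁴ grid resolution.

## Problem sizes

The shipped tests and scripts use worlds of 1–10 regions, 5-year steps over
2020–2050, monthly rotations of 10 and 30 years, 8-endpoint MACCs on 2–3
regions, and 100–1,000-draw property loops — sizes chosen so the full suite
documents the mechanisms in well under a coffee break while exercising every
code path.

## Known limitations

No trade or land-cover transitions between uses; no forestry (FOLU) CO₂;
no climate-change impacts on growth or SOC; no dis-adoption or permanence
risk within the horizon; no transaction, monitoring or institutional costs;
the non-CO₂ supply response is a reduced form. Magnitudes on the synthetic
world are therefore indicative only; the package's claims are about the
internal consistency and qualitative behaviour of the mechanisms.
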