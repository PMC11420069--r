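# agrimacc

Desk-scale economic modelling of CO₂ sequestration options on agricultural
land: enhanced soil organic carbon (SOC) management on cropland and pastures,
biochar application, and silvo-pasture systems. The package is aimed at
land-use and climate-policy modellers who want a transparent, fully synthetic
test bed for the mechanics that large partial-equilibrium land-use models use
to represent these technologies — saturating carbon dynamics, quadratic
adoption-cost calibration, feedstock competition, and the farmer/government
transfer accounting — without any external data dependencies.

## The model

**Carbon dynamics.** Adoption is tracked in vintages (cohorts). A cohort of
area *A* adopting option *i* in year *t₀* sequesters at a constant rate *qᵢ*
(tCO₂e ha⁻¹ yr⁻¹) while *t − t₀ < Tᵢ* and nothing afterwards, where the
saturation horizon *Tᵢ* is 20 yr for SOC options, 30 yr for biochar and the
30-year silvo-pasture system, and 10 yr for the 10-year bioenergy
silvo-pasture system (biomass equilibrium). Options are additive on
co-adopted land (SOC + biochar on cropland, SOC + silvo-pasture on pasture);
the two silvo-pasture variants exclude each other on the same hectare.

**Adoption.** Moving a share *a* of a land type into a practice costs
*C(a) = c₁a + (s/2)a²* per hectare. Under a GHG price *p* (USD₂₀₀₀ tCO₂e⁻¹,
linear ramp from 0 in 2030 to the scenario endpoint in 2050) the
profit-maximising share is

> a\* = clip((p·q + v − c₁)/s, 0, a_max)

with *v* the valued yield co-benefit (1.5 / 1.2 / 0.7 % yield per
tCO₂ ha⁻¹ yr⁻¹ in the AFR / LAM / ASIA region groups). The slope *s* of the
SOC cost curves is calibrated so that *p* = 100 USD₂₀₀₀ yields the maximum
adoption shares (90 % of cropland, 60 % of pasture). Adoption is myopic and
irreversible; running the model across price endpoints traces out a marginal
abatement cost curve (MACC).

**Biochar chain.** Feedstock carbon (0.45 tC tdm⁻¹) is retained at 50 % in
the char, of which 79.6 % is stored beyond 100 years — 0.18 tCe tdm⁻¹ at
display precision — at 35 USD₂₀₀₀ tCO₂e⁻¹ pyrolysis cost, with 50 % of the
feedstock returned as a bioenergy byproduct. Biochar competes for residues
and wood with livestock uses and exogenous bioenergy demand on a merit-order
market, so its economic potential shrinks when bioenergy demand rises.

**Silvo-pastures.** Tree strips on 25 % of the pasture hectare are grown with
a monthly light-use-efficiency simulator (GPP = α·APAR·∏ modifiers, NPP a
fixed fraction of GPP, allocation prioritising roots under harsh conditions),
with a eucalypt archetype in warm climates and poplar below 11 °C mean annual
temperature. Grazing biomass supply falls by 25 % on converted hectares.

**Economics.** Ex post, producers book turnover changes, GHG tax payments
(emissions × price) and carbon subsidies (removals × price); governments book
tax minus subsidy. Taxes and subsidies are transfers, so producer and
government net positions always sum to the turnover change.

## Worked example

```r
library(agrimacc)
w   <- generate_world(world_config(n_regions = 4, seed = 1))
run <- run_scenario(w, "agCO2", endpoint = 100)   # 100 USD2000 = 163 USD2022 by 2050
r50 <- run$model$reports[run$model$reports$year == 2050, ]
aggregate(flux ~ option, data = r50, FUN = sum)
#>            option      flux
#> 1         biochar 1639.9663
#> 2 silvo_bioenergy  131.0075
#> 3    silvo_carbon  770.8932
#> 4        soc_crop  822.4556
#> 5     soc_pasture  589.7505
cumulative_stock(run$model$ledger, 2050)   # 32816 MtCO2e over 2020-2050
run$net_option_revenue                     # 366.1 bn USD2022 (subsidy 644.5 - MACC cost 278.5)
```

The 2050 fluxes are MtCO₂e yr⁻¹ by option on the synthetic world (about
4 GtCO₂e yr⁻¹ in total here): cropland and pasture SOC reach their 90 %/60 %
caps by 2050, the silvo-pasture systems fill their joint 50 % pasture cap,
and biochar — viable only once the price clears its feedstock and pyrolysis
costs — is bounded by the residue market. A MACC across endpoints:

```r
build_macc(w, c(25, 50, 100, 200))
#>   endpoint price_2022 cumulative annual_2050
#> 1       25       40.8    10946.1       997.2
#> 2       50       81.5    17019.9      1884.9
#> 3      100      163.0    32816.3      3954.1
#> 4      200      326.0    56098.4      4331.6
```

Cumulative 2020–2050 mitigation rises monotonically with the price endpoint;
the annual 2050 flux need not, because higher prices pull adoption — and
hence saturation — forward.

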