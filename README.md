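# ejburden

Risk-based apportionment of coronary heart disease (CHD) burden from
traffic-related air pollutants — black carbon (BC) and nitrogen dioxide
(NO₂) — across census tracts, with environmental-justice (EJ) disparity
statistics. The package is aimed at environmental epidemiologists and
local health departments who have tract-level long-term exposure surfaces
(e.g. from land-use regression) and county crude disease rates, and want a
fast, transparent estimate of where the pollutant-attributable burden
falls — in particular, how much of it falls on EJ communities.

## The model

**EJ classification.** A tract is EJ-sensitive when ≥ 30% of residents are
non-white minority and/or ≥ 20% live below the federal poverty limit
(both thresholds configurable, comparisons inclusive). ACS margins of
error are handled via the 90% convention, CV% = 100·(MOE/1.645)/estimate.

**Disparity along the exposure continuum.** Tracts are rank-ordered by
exposure and cut into quartiles Q1–Q4 (lowest → highest). The relative
incidence of EJ tracts in quartile *i* is

```
RI_i = [ #EJ_i / (#EJ_i + #nonEJ_i) ] / [ #EJ_1 / (#EJ_1 + #nonEJ_1) ]
```

with 95% CIs by the Katz log-ratio method:
exp(ln RI ± 1.96·SE), SE² = (1−p₁)/(n₁p₁) + (1−pᵢ)/(nᵢpᵢ).

**Risk-based burden.** The county crude rate (cases per 100,000/yr)
becomes a baseline annual risk R₀ = rate/10⁵, anchored at the
population-midpoint exposure x_mid (half the county population lives at or
below it). With Δᵢ = (xᵢ − x_mid)/u and a literature effect estimate of
e % per increment u (e.g. 6% CHD mortality per 0.752 µg/m³ BC), each
tract's total risk is

```
compound (default):  r_i = R0 · (1 + e/100)^Δi
linear:              r_i = R0 · (1 + (e/100)·Δi)
```

The pollutant-specific component ρᵢ = rᵢ − R₀ is rebaselined against the
lowest exposed tract, ρ′ᵢ = ρᵢ − min ρ ≥ 0, and the tract burden is
bᵢ = ρ′ᵢ·popᵢ expected annual cases, summable county-wide or by EJ
status. Over a county-scale exposure span the two scaling modes agree to
well under 1%.

Everything runs without external data: `generate_county()` draws a
synthetic county calibrated to realistic tract statistics (402 tracts,
~1.2 M residents, 136 EJ tracts, lognormal exposure marginals coupled to
Spearman ρ = 0.58, EJ status skewed toward high exposure).

## Worked example

```r
library(ejburden)
tracts <- generate_county(synthetic_config(seed = 42))
res <- run_burden_analysis(tracts, "bc", "mortality")
res$burden
#> <burden_summary> bc / mortality (compound scaling)
#>   attributable cases/yr: 62.5 (2.77% of county cases)
#>   EJ tracts: 21.3 cases (34.0% of burden; 29.9% of population)
res$quartiles[, c("quartile", "n_ej", "ri", "ri_ci_low", "ri_ci_high")]
#>   quartile  n_ej    ri ri_ci_low ri_ci_high
#> 1        1    21  1        1          1
#> 2        2    25  1.19     0.715      1.98
#> 3        3    33  1.59     0.990      2.54
#> 4        4    57  2.74     1.81       4.16
res$comparison$p_value
#> 5.74e-09
```

Reading: BC above the level of the least-exposed tract accounts for about
62.5 expected CHD deaths per year (2.8% of all county CHD deaths implied
by the 187.7/100,000 crude rate). EJ tracts hold 29.9% of the population
but 34.0% of that burden; they are 2.7 times more likely to sit in the
highest exposure quartile than in the lowest (95% CI 1.8–4.2), and their
tract-level risk distribution is shifted upward versus non-EJ tracts
(Mann-Whitney p ≈ 6×10⁻⁹).

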