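---
title: "Risk-based CHD burden apportionment and EJ disparity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-based CHD burden apportionment and EJ disparity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ejburden)
```

## The problem

Large epidemiological studies relating long-term air-pollution exposure to
disease are slow and expensive; communities that already have a
high-resolution exposure surface (typically from land-use regression) and
routine county health statistics can instead *apportion* the county's
observed disease burden across tracts with a risk-based model, using
concentration–response effect estimates published elsewhere. `ejburden`
implements that pipeline for coronary heart disease (CHD) and two
traffic-related pollutants, black carbon (BC, µg/m³) and NO₂ (ppb),
together with the disparity statistics needed to ask who carries the
burden: environmental-justice (EJ) tracts — those with ≥ 30% non-white
minority residents and/or ≥ 20% residents in poverty — versus the rest of
the county.

## The risk model

Let $R_0$ be the county baseline annual per-person risk, obtained from the
crude rate as $R_0 = \text{rate}/10^5$ (e.g. 187.7 CHD deaths per 100,000
→ 0.001877). $R_0$ is a *total* risk — it contains every cause, not just
air pollution — and is anchored at the **population-midpoint exposure**
$x_{mid}$: tracts are sorted by ascending exposure and $x_{mid}$ is the
exposure of the first tract at which cumulative population reaches half
the county total. (The defining phrase "half at or below, half at or
above" admits either boundary tract; we take the first, with ties in
exposure broken by tract id, so the rule is deterministic.)

Given an effect estimate of $e\%$ per exposure increment $u$ and
$\Delta_i = (x_i - x_{mid})/u$, each tract's total risk is scaled as

$$r_i = R_0\,(1+e/100)^{\Delta_i} \quad\text{(compound, default)}$$
$$r_i = R_0\,(1+(e/100)\,\Delta_i) \quad\text{(linear)}$$

The pollutant-specific component is $\rho_i = r_i - R_0$ (zero at the
midpoint, negative below it); rebaselining against the lowest exposed
tract, $\rho'_i = \rho_i - \min_j \rho_j \ge 0$, expresses risk relative
to the cleanest observed exposure rather than to zero pollution — a
deliberate choice, since extrapolating a concentration–response function
to zero is the least defensible part of any such model. Tract burden is
$b_i = \rho'_i\,\mathrm{pop}_i$ expected annual cases (kept continuous;
rounding is a reporting decision).

**Why compound is the default.** The effect estimates are relative risks
from log-linear survival models, so per-increment compounding matches
their semantics; the linear form is retained because simple per-increment
proportional adjustment is equally common in risk assessment practice and
because, over a county-scale exposure span, the two agree to first order:
for $|\Delta|\,e/100 \le 0.1$ the risks differ by under 1% relative. Both
are exposed via the `scaling` argument, and the tests exercise both. In
linear mode a large negative $\Delta$ can push $r_i \le 0$; that raises an
error naming the tract rather than silently clipping.

Useful identities (all enforced by tests): $\min_i \rho'_i = 0$; adding a
constant to every exposure changes nothing downstream of the midpoint
(translation invariance); in linear mode the total burden has the closed
form $(e/100)(R_0/u)\sum_i \mathrm{pop}_i (x_i - x_{min})$, which the
pipeline reproduces to machine precision.

**Excluded pairings.** NO₂/hospitalization is disabled by default: the
source cohort study found no association for that pairing after
co-pollutant correction, so computing a burden for it would manufacture a
number from a null finding. `allow_excluded_pairings = TRUE` overrides
deliberately.

## Disparity statistics

Tracts are cut into exposure quartiles as contiguous rank blocks; when
$n$ is not divisible by 4 the larger blocks come first (402 → 101, 101,
100, 100), and ties are broken by tract id, so the partition is
deterministic. The relative incidence of EJ tracts in quartile $i$,
$RI_i = p_i/p_1$ with $p_i$ the EJ proportion in quartile $i$, gets a 95%
CI by the Katz log-ratio method,
$\exp(\ln RI \pm 1.96\,SE)$, $SE^2 = (1-p_1)/(n_1 p_1)+(1-p_i)/(n_i p_i)$.
Katz is the standard risk-ratio interval and reproduces the asymmetry
typical of published RI intervals; it requires $\#EJ_1 > 0$, and the
package refuses (with guidance) rather than applying a hidden continuity
correction. A `significant` flag marks CIs excluding 1; because the
intervals themselves are returned, a pairwise CI-overlap rule can be
applied instead when comparing quartiles to each other.

EJ vs non-EJ tract risk distributions are compared with a two-sided
Mann-Whitney U test (exact for small untied samples), reported with each
group's median and IQR. Normality is assessed with the D'Agostino–Pearson
omnibus $K^2$ (implemented here from the standard skewness and kurtosis
transformations and cross-checked against an independent reference
implementation); it is undefined below $n = 8$ and skipped with a warning
there. If every pooled value is identical the U statistic is reported at
its null mean $n_1 n_2/2$ with $p = 1$, since the tie-corrected normal
approximation degenerates.

## EJ classification and ACS uncertainty

Thresholds are inclusive (≥), matching the regulatory phrasing
"greater than or equal to". The MOE→SE divisor is 1.645 (the ACS 90%
convention) and is an argument, since agencies do not always document
their convention. Two survey vintages combine as the arithmetic mean with
independent-error MOE propagation $\sqrt{m_1^2+m_2^2}/2$. No CV% exclusion
threshold is applied by default: high CVs concentrate in low-income,
minority and urban tracts, so excluding them would itself bias an EJ
analysis; `cv_percent()` exists precisely so users can *flag* rather than
drop.

## Exposure aggregation

Fine rasters are down-averaged by block means (each coarse cell is the
arithmetic mean of its $f \times f$ fine cells, conserving the grid mean
exactly) and tract exposure is the arithmetic mean of all member cells;
cells belong wholly to one tract and out-of-county cells carry a sentinel
label. Upstream LUR systems sometimes average buffer predictions at a
lattice of nodes *within* each coarse cell rather than averaging sub-cells;
the sub-cell mean used here is the simpler convention and coincides with
node averaging as the node spacing matches the fine-cell size. Tracts with
zero cells are returned in an exclusion list, never silently dropped.

## The synthetic county

`generate_county()` exists so every stage is testable without external
data. Its defaults are the package's calibration conditions, chosen once:
402 tracts, ~1.2 M residents, 136 EJ tracts, population-weighted 18.8%
non-white and 13.1% poverty, BC mean 1.05 µg/m³ (IQR 0.22), NO₂ mean
4.96 ppb (IQR 2.47), inter-pollutant Spearman 0.58, and ACS-style poverty
CVs near 33%. Design choices:

* **Lognormal exposure marginals**, matched to the mean and IQR (positive
  support and right skew are what urban LUR surfaces show; only those two
  summaries are available as targets). A Gaussian copula couples the two
  pollutants; the latent correlation starts at the asymptotic value
  $2\sin(\pi\rho_S/6)$ and is then fine-tuned against the sample's own
  realized rank correlation, so the finite county hits the target Spearman
  rather than merely matching it in expectation.
* **Populations** are lognormal with a linear thinning toward high
  exposure (the emulated county houses roughly twice as many residents in
  its least-exposed quartile as its most-exposed) and rescale to the
  county total within 1%.
* **Demographics** follow a logistic link from the combined exposure rank
  with slope `ej_exposure_skew` plus beta noise. The two intercepts are
  solved at generation time so the population-weighted fractions hit
  their targets; the beta precision is then rescaled so the *expected* EJ
  count equals `target_ej_count`, and the realized count is nudged exactly
  to target by adjusting counts only in tracts within ±2 percentage
  points of a threshold (preserving the exposure–demographics dependence).
  If the band cannot absorb the gap — possible in very small counties —
  the generator warns and reports the realized count.
* **The default skew of 1.2** was chosen, once, because it reproduces the
  realistic quartile EJ profile (about 17/25/35/59 EJ tracts from Q1 to
  Q4, RI₄ ≈ 3–5); skew 0 makes EJ status exposure-independent, which the
  permutation-null tests rely on.

`generate_grid()` lays tracts out as square blocks on a lattice and adds
spatially smoothed multiplicative noise (default 1.5% amplitude), so
tract-mean aggregation recovers the table exposures exactly at zero noise
and within about 1% otherwise. The geography is deliberately schematic:
no road networks, point sources, river valleys or spatial autocorrelation
*between* tracts. Consequently, passing tests demonstrate the pipeline's
algebra and statistics, not that any real county's exposure pattern is
reproduced.

## Numerical choices and problem sizes

Lognormal σ is solved by `uniroot` on the IQR/mean ratio (tolerance
1e-12); logistic intercepts likewise (1e-10). Quartile and midpoint
tie-breaks are by tract id. Unit conversion uses a molar volume of
24.45 L/mol (25 °C, 1 atm) — published equivalences rounded from slightly
different conditions are matched within 1% — and the constant is an
argument. The test suite runs stochastic properties at the sizes a laptop
handles in seconds: 1,000 label permutations for the RI null, 200
replicate counties for the skew-zero mean, 30-replicate ensembles per
skew level for monotonicity.

## Limitations

Single-pollutant burdens are computed independently and are additive by
assumption; no threshold or supralinear concentration–response forms; no
age stratification of the baseline rate (county crude rates flatten real
demographic risk gradients, which likely *understates* EJ disparities);
effect estimates are imported from a different city and era, which is why
`sensitivity_substitution()` propagates the meta-analytic hazard-ratio
spread into a burden range rather than trusting a single estimate.
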