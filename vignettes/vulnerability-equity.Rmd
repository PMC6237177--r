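---
title: "Measuring geographic inequity in health-service availability with a composite vulnerability index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring geographic inequity in health-service availability with a composite vulnerability index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vulnindex)
```

## The problem

Publicly funded hospital-insurance schemes aim to equalize *financial*
access to care, but care must also be *available*: an enrolled household in
a district with no empanelled hospital has coverage in name only. Because
deprivation clusters geographically, the districts in greatest need are
often exactly those with the fewest providers — the Inverse Care Law.
`vulnindex` implements the standard aggregate-data workflow for
quantifying this: a composite vulnerability index over districts, tertile
grouping, availability and utilization rates per 100,000 enrolled, pairwise
inequality measures, and correlation analysis. Its packaged worked case is
Chhattisgarh state, India (27 districts, RSBY/MSBY universal scheme,
financial year 2015–16).

## The index

Five district indicators enter the default index
(`default_indicator_specs()`): Scheduled Caste/Tribe population share,
un-irrigated net sown area, female illiteracy, rural population share, and
the district's year of formation, all in the orientation "higher = more
vulnerable" (a *later* formation year means a newer district with less
established infrastructure). Each indicator is min–max normalized across
districts,

$$Y_i = \frac{X_i - X_{\min}}{X_{\max} - X_{\min}} \in [0, 1],$$

after orientation (indicators flagged `lower_is_more_vulnerable` are
negated first, so 1 always marks the most vulnerable district). The
composite index is the **unweighted sum** of the k normalized values, so it
ranges over $[0, k]$. The HDI convention is often stated as an unweighted
*average*; sum and mean give identical ranks and groups, and the published
Chhattisgarh index values (maximum 4.9 on five indicators) are on the sum
scale, so the sum is the default and `aggregate = "mean"` is an option.
Equal weights reflect the design premise that the deprivation dimensions
are not ordered in importance; `weights` provides a pass-through for
sensitivity analysis, not a recommendation.

Normalization makes the index invariant to positive affine rescaling of any
raw series (unit changes do not move ranks) — a property the test suite
checks on random tables. A constant indicator ($X_{\max} = X_{\min}$) is a
hard error: it carries no ranking information, and silently dropping or
zero-filling it would change the index scale.

### Ranking, groups and ties

Districts are sorted by index value, descending, and cut into contiguous
groups of near-equal size (tertiles by default; any group count works).
When N is not divisible by the group count, the extra districts go to the
*most*-vulnerable groups first — conservative in the direction of flagging
vulnerability. Ties are broken by district name, ascending, so results are
deterministic and documentable.

One consequence for the packaged case: Bemetara and Balodabazar are both
printed with index 2.9 at the tertile boundary. The published grouping
placed Bemetara in MVD and Balodabazar in LVD, presumably on unrounded
values that were never published; the package's name-order rule reverses
those two labels when regrouping from the printed one-decimal index. The
tertile sizes (9/9/9) and the per-tertile index ranges (4.9–3.7, 3.6–2.9,
2.9–0.2) are unaffected, and the fixture retains the published labels.

## Scheme indicators and pooling

Availability (empanelled hospitals) and utilization (claim counts, claim
amounts in INR) are expressed per 100,000 **enrolled persons**, not per
census population: dividing by enrolment holds the opportunity to use the
scheme equal across groups, leaving availability as the quantity compared.
Claims are attributed to the district of the *hospital* filing them, so
the indicators describe service provision located in a district, not the
care its residents obtained elsewhere.

Group and state rates are **pooled**: numerators summed over member
districts, divided by summed enrolment. Pooling is the standard rate
construction (equivalently an enrolment-weighted mean of district rates)
and is consistent with the published state totals (735 hospitals, 12.5
million enrolled, 5.9 per 100,000). Three invariants are property-tested:
group numerators sum to the state numerator; doubling numerators doubles
rates; and a pooled rate always lies within the span of its member
districts' rates. Claim amounts are reported in units of INR 100,000 per
100,000 enrolled, matching the published tables.

## Inequality measures

Two pairwise measures, computed LVD:HVD and MVD:HVD for every indicator:
the **ratio** (relative inequality) and the **difference** (absolute
inequality). Ratios are computed from full-precision rates and only rounded
for display (`display_value`); a zero reference rate yields an `NA` flagged
`defined = FALSE` rather than an infinity, so non-finite values never
propagate into reports. The published tables print only ratios; differences
are reported by the package as well but have no printed counterparts to
compare against. No concentration index, slope index, or Gini is provided —
the two simple measures are the method here.

## Correlation analysis

Association between the index and each district-level rate uses Pearson's
product-moment correlation across districts. The published analysis states
the estimator and the 0.05 significance level but not the p-value or CI
constructions; the package adopts

- two-sided t-test: $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df, and
- Fisher-z interval: $\tanh(\operatorname{atanh} r \pm z_{0.975}/\sqrt{n-3})$,

because both reproduce the published values exactly at printed precision
(p = 0.032 at r = 0.414, n = 27; lower limit −0.788 at r = −0.583). They
are the conventional choices, but their status here is *inferred from
numerical agreement*, and they are documented as such. No multiple-testing
correction is applied, matching the per-row 0.05 flags of the source
analysis. An indicator that is constant across districts gets an undefined
row rather than failing the whole table.

Because the packaged district table carries rates printed at one decimal,
recomputed correlations can differ from the published ones in the third
decimal; the acceptance suite allows ±0.02, and four of the six rows agree
at three decimals anyway.

## Geographic export

`build_choropleth()` joins fitted scores (and any rate records) onto a
GeoJSON FeatureCollection by district name — case-insensitive, whitespace
normalized — and writes plain GeoJSON (WGS84 lon-lat assumed, geometries
untouched). The vulnerability class travels as a `tertile` *property*, not
a colour: styling belongs to the downstream viewer, and properties are
testable. The original analysis used a government shapefile that cannot be
redistributed, so the package generates synthetic square-grid boundaries
(`synthetic_boundaries()`), clearly labelled synthetic, for tests and
demonstrations. Partial joins warn and are reported per feature; a join
that matches nothing is an error.

## The synthetic generator

`generate_state()` emulates the statistical structure the analysis is
designed to detect, on an abstract plane with the capital at the centre:

| parameter | default | meaning |
|---|---|---|
| `n_districts` | 27 | districts, placed uniformly on the unit disk |
| `gradient_strength` | 1 | latent vulnerability per unit distance from centre |
| `latent_noise_sd` | 0.2 | non-spatial vulnerability noise (index units) |
| `beta_private` | −1 | log effect on private-hospital density, per SD of vulnerability |
| `beta_public` | 0 | same, public sector |
| `coverage_slope` | 0.15 | logit effect on enrolment coverage (positive = pro-poor) |
| `enrolment_base` | 0 | logit baseline coverage (0 → 50%) |
| `base_density` | 2.2 / 3.7 | public/private hospitals per 100k enrolled at mean vulnerability |
| `claims_per_hospital_mean` | 650 / 1100 | mean annual claims per public/private hospital |
| `cost_per_claim_mean` | 5500 | mean INR per claim |
| `census_population_mean` | 850,000 | log-normal district population around this mean |

The defaults encode the Chhattisgarh-like regime — a centre-periphery
vulnerability gradient, flat public density, strongly declining private
density, mildly pro-poor enrolment — with magnitudes (densities, claims per
hospital, cost per claim, populations) set to the state-total scale of the
published tables. The five raw indicators are monotone noisy Gaussian
transforms of the latent vulnerability, clipped to their supports;
enrolment is binomial with logistic coverage; hospital counts are Poisson
with log-linear density; claims are Poisson per hospital; amounts are
claims × Gamma cost. These are the simplest forms with the right supports —
the real data are administrative and specify no distributions.

What the generator does **not** emulate: spatial autocorrelation beyond the
radial gradient, district size–vulnerability correlation, sector-specific
claim-cost differences, reporting artifacts, or calibration to any real
state's exact magnitudes. Passing recovery tests therefore show that the
pipeline recovers planted monotone structure of realistic magnitude from
Poisson-noisy counts at N = 27 — not that it is robust to everything real
administrative data can do.

`recovery_experiment()` reruns the *full* pipeline (index fitted from the
raw indicators → tertiles → pooled rates → LVD:HVD ratio → correlations) on
replicate panels, seeds derived as root seed + replicate, and reports sign
recovery and the mean private-availability ratio. Under the default regime
the private-sector correlation is negative in effectively all replicates
and the mean LVD:HVD private ratio is far above 1; under an all-null
configuration the sign is negative about half the time and the mean
log-ratio is within Monte-Carlo error of zero. The shipped checks use 200
replicates of 27 districts (seconds of runtime), a size at which the
Monte-Carlo standard error of a 95% sign-recovery proportion is about 1.5
points.

## Numerical and design notes

- **Tie-break**: full-precision index descending, then name ascending.
- **Degenerate inputs**: constant indicators, zero enrolment, zero-sector
  totals and perfect correlations are errors or flagged degenerate values,
  never silent numbers.
- **Missing data**: rejected at table validation. A 27-row administrative
  table should be complete; imputation inside an equity analysis would
  manufacture certainty.
- **Rounding**: all statistics are computed at full precision; rounding
  happens only in display columns and printed output.
- **Reproducibility**: every stochastic path flows from one integer seed;
  generation restores the caller's RNG state.

## Limitations

The index cannot be validated against individual-level outcomes (the data
are aggregate), and the packaged fixture carries only the printed
one-decimal values — the unrounded indicator inputs behind the published
index were never released, so the index is *not* reconstructable from the
fixture and fixture-based analyses start from the printed index column.
That limitation is inherent to the source material, and the package states
it rather than hiding it: index construction itself is exercised and
property-tested on synthetic and user data instead.
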