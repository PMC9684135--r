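---
title: "VPD thresholds for forest fire activity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{VPD thresholds for forest fire activity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firethresh)
```

## The scientific problem

Dead fine fuels on the forest floor gain and lose moisture with the
atmosphere, and their moisture content gates whether an ignition becomes a
fire. Vapour pressure deficit (VPD) — the gap between the saturation vapour
pressure at air temperature and the actual vapour pressure — is a direct
measure of atmospheric drying power and a strong predictor of dead fuel
moisture. `firethresh` implements a complete, testable pipeline around one
central idea: that for a given forest biome and region there is a critical
daily maximum VPD above which fire becomes more likely than not, and that
climate change shifts how many days per year sit above that threshold.

The pipeline has five scientific stages:

1. **VPD computation** from sub-daily temperature and humidity fields,
   using the value of humidity *at the time of the daily temperature
   maximum*.
2. **Occurrence sampling**: presence rows from burned-area records matched
   to same-day VPD at the nearest climate cell, balanced by quasi-absence
   rows from unburned cells at random dates, with a five-year burn
   exclusion.
3. **Threshold model**: a binomial-logit GLM of occurrence on daily VPD per
   stratum; the threshold is the VPD at 50% fitted probability.
4. **Bias correction**: empirical quantile mapping of model VPD onto a
   reference climatology, with change always reported as modelled future
   minus modelled present (the delta convention).
5. **Exposure**: change in annual threshold-exceedance days multiplied by
   population or aboveground-biomass rasters.

A seeded synthetic-data module generates statistically structured stand-ins
for every external dataset, so the full pipeline runs and is validated
offline.

## The threshold model

For rows $(v_i, y_i)$ with $y_i \in \{0,1\}$ indicating fire occurrence and
$v_i$ the daily maximum VPD (kPa),

$$\operatorname{logit} P(y_i = 1) = \beta_0 + \beta_1 v_i ,$$

fitted by maximum likelihood (IRLS as implemented in `glm`, log-likelihood
tolerance $10^{-8}$, at most 100 iterations). The critical threshold is the
unique 50% crossing

$$\mathrm{VPD}_{P=50} = -\beta_0 / \beta_1, \qquad \beta_1 > 0 .$$

Its standard error comes from first-order (delta-method) propagation of the
coefficient covariance $V$ through the ratio: with gradient
$g = (-1/\beta_1,\; \beta_0/\beta_1^2)$, $\mathrm{SE} = \sqrt{g^\top V g}$,
and the reported interval is $\pm 2\,\mathrm{SE}$. The test suite
cross-checks this against a 500-replicate nonparametric bootstrap (they
agree within 10% at $n = 1500$).

Model skill is summarised three ways:

* **AUC** of the ROC curve, by trapezoidal integration over unique score
  values. This credits ties with half weight and is numerically identical
  to the Mann–Whitney pair statistic, which the tests verify by brute-force
  pair enumeration (and against pROC).
* **TPR**, the fraction of burned rows with fitted probability at least
  0.5 — the probability of correctly predicting fire on a fire day. A
  fitted probability of exactly 0.5 counts as a positive prediction; with
  a single increasing predictor this is equivalent to classifying by
  VPD $\ge$ the threshold itself.
* **Percent deviance explained**, $100\,(1 - D/D_0)$ against the
  intercept-only null.

**Perfect separation.** When every burned row is drier than every unburned
row the slope is unbounded. Rather than fail, the fit is flagged
(`separated = TRUE`), the threshold is reported as the midpoint of the
separating gap, the interval is omitted, and AUC/TPR take their limiting
values. A response that *decreases* with VPD is an error, not a model.

**The case-control caveat.** Balanced presence/quasi-absence sampling is a
case-control design: it leaves the slope unbiased but shifts the intercept
by the log ratio of sampling fractions, and with it the 50% crossing. When
fire days and non-fire days are sampled from a design symmetric about the
threshold the shift vanishes — the recovery tests use uniform VPD on
$(0, 2\,\mathrm{VPD}_{P=50})$ for exactly this reason. In the fully
synthetic end-to-end world, where fire is rare per cell-day, the fitted
threshold is the balanced-design threshold, systematically below the
planted per-cell-day 50% point; this is a property of the sampling design
itself, shared by any analysis built on balanced quasi-absences, and the
reported threshold should be read in that design's terms.

## VPD computation

Saturation vapour pressure uses the Magnus/Tetens form over liquid water,

$$e_s(t) = 0.6108 \exp\!\left(\frac{17.27\,t}{t + 237.3}\right) \text{ kPa},$$

the standard choice in fuel-moisture work; differences against other
curves are far below model noise, and the function is a single swappable
unit. Two humidity variants are supported:
$\mathrm{VPD} = e_s(t) - e_s(t_d)$ from dew point (reanalysis-like hourly
input) and $\mathrm{VPD} = e_s(t)(1 - \mathrm{rh}/100)$ from relative
humidity (3-hourly GCM-like input).

The daily value takes the sub-daily step at which temperature peaks
(earliest step wins ties — deterministic and documented) and computes VPD
from the temperature–humidity pair *at that step*. This is deliberately
not the day's maximum pointwise VPD; a crafted-day unit test pins the
convention. Day boundaries follow the grid's native time axis; no
solar-time correction is applied. Relative humidity marginally above 100%
(input rounding) is clamped to saturation with a reported count; above
100.5% is an error.

## Sampling rules

* **Nearest cell**: great-circle distance to climate-cell centres;
  ties break to the lowest latitude index, then longitude index. Several
  fire-product cells may map to one climate cell-day; each keeps its own
  presence row.
* **Five-year exclusion**: a cell is eligible as an absence on date $d$
  only if it has no recorded burn in $[d - 5\text{yr}, d)$ and is unburned
  on $d$ itself. Users supply pre-period history or accept left-censoring
  (logged). The window is half-open: a burn exactly five years prior
  excludes.
* **Balance**: for every stratum and calendar year, exactly as many
  absences as presences — and hence overall. Absence dates are uniform
  over the year's days (not fire-season weighted), cells uniform among
  those eligible on the drawn date, pairs drawn without replacement; a
  duplicated (cell, date) pair would add rows without information.
  Exhausted pools fail loudly with the stratum and year named.

## Bias correction and the delta convention

Empirical quantile mapping with 99 percentile levels: model-historical and
reference quantiles are tabulated at shared levels, application
interpolates linearly between (source, target) pairs, values beyond the
outermost level are corrected by that edge's additive offset, and output
is clamped at 0 kPa. The map is fitted per calendar month by default (an
all-year switch exists and both paths are tested); per-month fitting is
the common practice where bias varies seasonally. A constant source series
has no quantile structure and receives a flagged identity-with-offset map.

One propagation property deserves explicit statement: under a
multiplicative bias $s$, plain empirical quantile mapping compresses an
additive model-space climate-change signal $\delta$ to $\delta/s$ in
corrected units. This is the textbook behaviour of the method (it is the
motivation for trend-preserving variants such as quantile delta mapping,
which are out of scope here), and the tests assert it quantitatively
rather than pretending the signal is untouched.

Change is always **modelled future minus modelled present** — the observed
climatology never enters the difference, so constant model bias cancels.
The difference is taken on the derived exceedance-day statistic (the
mapped change in "days over threshold"), not on raw VPD.

## Exceedance and exposure

An exceedance day is a day with daily maximum VPD **strictly greater**
than the cell's threshold; boundary days have measure zero in continuous
data. Thresholds are painted from strata onto cells via the stratum map;
cells outside every stratum are missing, never zero, and climatologies
fitted under different threshold maps refuse to be differenced.

Density rasters (persons or tonnes of aboveground biomass per cell, the
per-cell convention making the products person-days and tonne-days)
resample to the climate grid by the **median of positive values**; zeros
are the fine products' missing-data code and are omitted, and an all-zero
block is missing. Exposure is the elementwise product of the change in
annual exceedance days with the resampled density — bilinear, sign-
following, zero where density is zero.

## What the synthetic generator does and does not emulate

The generator produces: temperature with sinusoidal annual and diurnal
cycles plus AR(1) noise (per-cell, lag-1 correlation 0.7 by default) and a
shared regional AR(1) anomaly for spatial coherence; dew point as
temperature minus a non-negative depression, so dew point never exceeds
temperature by construction; fire occurrence as independent Bernoulli
cell-days under a planted logistic law; GCM-like series as a retained
affine distortion (scale, then shift) of the reference with a constant
future shift; and log-normal density rasters with a planted fraction of
exact zeros, nested an integer number of times in the climate grid. A
direct daily-VPD generator with a Gaussian AR(1) marginal exists so that
exceedance probabilities have a closed form for oracle tests. Everything
runs on a 365-day no-leap calendar (leap-day inputs map to 28 February),
and every generator is bit-reproducible under its seed.

Deliberately not emulated: fire spread and spatial contagion, fuel
accumulation and ignition sources, topography, realistic population
projections, leap years, and any weather-model-grade spatial covariance.
Passing tests therefore demonstrate the correctness of the statistical
machinery under known laws — threshold recovery, interval calibration,
filter exactness, distortion recovery, exposure algebra — not the realism
of any particular Earth dataset.

**Default study conditions.** The pipeline's default world is an 8×8 grid
over five years at 3-hourly resolution, with the planted per-cell-day law
chosen so fire is rare per cell (about 0.2 burns per cell-year, threshold
in the far upper tail of the VPD climate). Real burned-area products burn
a small fraction of forest cells in any year, and rarity is what makes the
five-year exclusion meaningful — a world where every cell burns annually
has no eligible quasi-absences. Test and acceptance runs use worlds from
2×2 to 20×20 cells and one to five years, with model fits at
$n = 10^4$ rows (and one $10^6$-row check of the large-sample interval
regime); these sizes were chosen as the smallest at which the sampling
error of each check is comfortably below its assertion margin.

## Numerical choices

* IRLS convergence $10^{-8}$ on the log-likelihood, 100 iterations max.
* ROC on unique score values; trapezoidal integration; ties half-credit.
* Predicted probability exactly 0.5 counts as a positive prediction.
* Quantile type 7 (R's default) for the empirical quantiles of both
  series in the map.
* Interpolation nodes are honoured exactly: a value equal to a stored
  source quantile maps to the stored target quantile.
* Stage seeds derive from the master seed by fixed offsets, so any stage
  can be reproduced in isolation; no stage reads ambient entropy.
* Equidistant nearest-cell ties, daily temperature-maximum ties, and
  assembly shuffling are all deterministic.

## Limitations

Single-predictor models only: evaporation, soil moisture, wind and
multi-predictor aggregation are out of scope, as are spatial random
effects and regularisation. No smoke transport or health/carbon impact
conversion is attempted — exposure units (person-days, tonne-days) are
transparent products, nothing more. Quantile mapping here is the plain
empirical variant; trend-preserving and multivariate corrections are not
implemented. The artifact formats are plain-text CSV serialisations of
grids, events, samples and rasters rather than NetCDF/GeoTIFF containers;
the schemas are documented and validated by `validate_io()`.
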