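---
title: "Calibrating and verifying fire-danger classes with firecal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating and verifying fire-danger classes with firecal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firecal)
```

## Why calibrate a fire-danger index

The Canadian Fire Weather Index condenses temperature, humidity, wind and
recent rainfall into a single dimensionless rating. Its link to actual fuel
state is weak by construction, so a fixed FWI value maps onto very different
fire behaviour in different ecosystems: warning levels devised for a boreal
jack-pine stand do not transfer to the Mediterranean. `firecal` derives
*area-specific* danger-class boundaries from a multi-year daily FWI record
and then checks, against gridded burned-area observations, whether
exceedances of those boundaries actually detect large fires.

## The calibration model

### The extreme FWI

The anchor of the class ladder is the **extreme FWI** of the area. For each
season-year we pool every valid cell-day value of the (masked, cropped,
fire-season) record and take the percentile

$$p = 100\left(1 - \frac{\texttt{ndays}}{N}\right),$$

where $N$ is the calendar length of that year's fire season in days and
`ndays` is the number of days per year on which a fire is expected to occur.
With the defaults — `ndays = 4` and the northern-hemisphere season
(1 April – 31 October, $N = 214$) — this is $p \approx 98.1$, i.e. the
yearly ~98th percentile: the FWI exceeded on roughly the four most severe
days of a year. The extreme is the **median across season-years** of these
yearly percentiles, which makes it robust to a single anomalous year.
Recomputing $p$ from $N$ each year keeps the interpretation of `ndays`
("expected fire days") exact for wrapped southern seasons and custom season
windows of any length.

### From intensity ratios to FWI thresholds

Fire severity is naturally expressed through fire-line intensity $I$ (kW/m
scale), which relates to FWI through the published exponential pair

$$I = \frac{e^{0.980(\ln \mathrm{FWI})^{1.546}}}{0.289}, \qquad
  \mathrm{FWI} = e^{1.013\,(\ln 0.289 I)^{0.647}}.$$

These are *near*-inverses: the round trip FWI → I → FWI deviates by less
than 1% over FWI ∈ [2, 120] (the suite checks 0.13% max on a 1000-point
sweep), but not exactly zero, which is why both the rounded and the raw
thresholds are retained. Classes are spaced by a **constant intensity
ratio** `ratio` (default 5): the extreme is transformed to $I_5$, the lower
boundaries are $I_k = I_5 / r^{5-k}$, and each is transformed back to FWI.
Spacing in $I$ rather than in FWI reflects the exponential growth of fire
behaviour with intensity. With an extreme of 33 and $r = 5$ the rounded
ladder is (2, 5, 10, 19, 33), separating the six classes *very low* to
*extreme*; class membership uses half-open bins
$[\theta_{k-1}, \theta_k)$, with values at or above the last boundary
classed *extreme*.

`ratio = 5` is the package default because it is the unique small integer
ratio that reproduces the (2, 5, 10, 19, 33) ladder from an extreme of 33
under integer rounding; it is an ordinary tunable parameter, and areas with
flatter or steeper climatologies may prefer other values. `ndays` is the
parameter most worth eliciting from local expertise.

### Pooling choice

One threshold vector describes one area, so the yearly percentile pools all
cells of the region into a single sample (`pooling = "pooled"`). An
alternative — percentile per cell, then the median across cells — is
available as `pooling = "percell"`; it weighs cells equally regardless of
how many valid days each contributes and is less sensitive to spatially
heterogeneous missingness. Pooled is the default because the calibrated
quantity ("the FWI exceeded on the worst few days somewhere in the area")
is a property of the area's pooled distribution. The minimum area is one
grid cell.

## The verification procedure

Verification deliberately uses the **whole year**, not just the fire
season: a threshold that fires in January should be credited or penalised
for it. The steps, in order: binarize observations at `obs_threshold`
(default 50 ha — only large fires are informative at coarse resolution);
binarize the index at the danger threshold under test; intersect the two
date axes; if the observation grid is finer, resample the *binary*
observations onto the index grid by nearest neighbour (binarize-then-
resample keeps the field binary; the converse would average hectares across
cells); drop (day, cell) pairs missing on either side; cross-tabulate.

POD follows the conventional rounding `round(hits/(hits+misses), 2) * 100`,
so it is reported in whole percent. Summing per-country contingency counts
(`sum_contingency()`) gives an "area as the sum of its parts" total whose
POD generally differs in the last digit from the POD of the area verified
as one piece — both aggregations are legitimate and both are exposed.

For the ROC curve the raw FWI values serve as scores against the binary
observations; the curve sweeps every distinct score as a threshold and the
AUC is the midrank Mann–Whitney statistic. Using the raw index (rather than
the binarized prediction) is the standard construction that yields a single
curve per system, of which each published threshold is one operating point.

## Numerical and interface choices

* **Percentiles** use linear interpolation of order statistics with the
  $k$-th of $n$ values at fraction $(k-1)/(n-1)$ (`stats::quantile`
  type 7); the rule is configurable in `percentile_raster()`. Missing
  values are dropped per cell; a cell with fewer than `min_valid` samples
  reports `NA`.
* **Coordinates** are normalized on ingest to WGS84 with longitudes
  ascending in [−180, 180); `rotate_longitudes()` is a pure column
  permutation (no interpolation) and is idempotent.
* **Cell inclusion** under a polygon uses the cell-center rule by default
  (deterministic, resolution-independent); points exactly on an edge count
  as inside. An `"any"` mode keeps a cell if its center or any corner is
  inside, approximating fractional overlap. Containment uses the even-odd
  rule, so interior rings act as holes and multipart regions union
  naturally.
* **Cropping** snaps the bounding box outward to whole cells — no partial
  cells are ever created, and cropping is idempotent.
* **Nearest-neighbour ties** resolve to the lower-index source cell
  (deterministic).
* **Stacking** many daily NetCDF files trusts lexicographic filename order
  (the usual convention for daily archives); `sort_by_date = TRUE` orders
  by each file's first date instead. Gaps in the merged axis are surfaced
  as an error, never interpolated; sub-daily axes are rejected by the
  strict-increase invariant.
* **Dates** come from the CF time coordinate (`days/hours/seconds since`),
  else from an explicit `dates =` argument; there is no silent default.
* **Season endpoints** are inclusive on both sides; a wrapped season is
  labeled by the year containing its start. Custom `fss`/`fse` are
  month-day recurrences — a full date is accepted but only its month and
  day are used.
* **Rounding** of thresholds to integers (the conventional published form)
  can collapse neighbouring classes when the extreme is small; the
  constructor then fails loudly rather than emitting a non-increasing
  ladder, and raw thresholds are always available.

## What the synthetic generator does and does not emulate

`sim_spec()` + `make_fwi_cube()` + `make_burned_area_cube()` stand in for a
multi-decade reanalysis and a satellite burned-area product. They emulate
the statistical features the methods actually consume:

* non-negative, right-skewed daily FWI marginals (gamma, shape 1.2) whose
  scale grows toward the equatorward edge — so nested sub-regions have
  stochastically ordered climatologies;
* a sinusoidal seasonal modulation peaking mid fire season
  (`seasonal_amplitude = 0` switches it off, leaving i.i.d. gamma cells
  with closed-form quantiles for oracle checks);
* daily fire occurrence with probability `plogis(a + b·FWI)` (defaults
  a = −4, b = 0.12, i.e. a few-percent base rate rising steeply across the
  upper danger classes) and log-normal fire sizes with median 10 ha and
  σ(log) = 1.91, placing ≈20% of events above the 50 ha large-fire cutoff
  so the cutoff is meaningful at small sample sizes;
* an observation grid finer than the index grid by an integer factor
  (default 3) to force the resampling path.

They do **not** emulate spatial or temporal autocorrelation of fire
weather, fire spread across cells, persistence of burned area, observation
error in the satellite product, or trends in the climatology. Passing tests
therefore demonstrate the correctness of the algorithms and the
recoverability of planted statistical structure, not skill on real data.
The gamma family is "heavy-tailed" only in the practical sense of strong
right skew; users wanting polynomial tails can plug a different marginal by
generating their own cube.

Generators are pure functions of the spec: the RNG state of the caller is
saved and restored, and the same spec yields bit-identical cubes.

## Problem sizes in the test suite

The suite favours sizes where independent oracles are exhaustive or
analytic: brute-force pairing equivalence at 10×10×30; percentile oracles
on single cells and 3×3 grids of 100 days; pooled-extreme recovery on
7×7 cells × 214 in-season days × 5 years (≈10⁴ cell-days/year) against the
analytic quantile of the gamma mixture, at 2% tolerance; ROC behaviour at
~1.1×10⁵ paired samples, where a null link's AUC lies within 0.48–0.52 and
a planted positive link clearly exceeds it. Per-cell sample-quantile
convergence is asserted within four standard errors of the order statistic
rather than a fixed percentage, since the tail quantile's sampling error at
10⁴ days is itself of order 1.7%.

## Known limitations

* Thresholds are as good as the record they are calibrated on: a coarse
  (~80 km) reanalysis cannot resolve sub-regional variability, so regional
  and provincial ladders inside the same grid cells come out nearly equal.
* Calibration assumes a stationary climatology; under climate change the
  extreme should be recomputed as the record extends.
* Region polygons are read from GeoJSON; ESRI shapefile input is not
  supported.
* The nearest-neighbour rule is the only regridding offered — appropriate
  for binary fields, too crude for conservative regridding of continuous
  fluxes.
* `ndays` and `ratio` defaults are sensible continental-scale starting
  points, not local truth; operational use should tune them with local
  expertise and re-verify.
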