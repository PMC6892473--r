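---
title: "Assessing wildland-fire smoke exposure from paired model runs"
author: "firePM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing wildland-fire smoke exposure from paired model runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firePM)
```

## The problem

Wildland-fire smoke is a large and growing source of fine particulate
matter (PM2.5), but routine monitor networks are sparse exactly where fires
burn, sample on 1-in-3 or 1-in-6 day schedules, and cannot by themselves
attribute measured PM2.5 to fire. Chemical-transport models offer complete
space-time coverage and a clean attribution device: run the model twice,
once with all emission sources and once with fire sources removed. The
difference of the two gridded fields,

$$ C_{\mathrm{fire}}(s, t) \;=\; C_{\mathrm{all}}(s, t) - C_{\mathrm{nofire}}(s, t), $$

is the fire-attributable PM2.5 at grid cell $s$ on day $t$ (the
"brute-force zero-out" attribution). firePM implements the downstream
exposure-assessment arithmetic on such paired daily fields: aggregation to
administrative units, annual exposure classes, multi-day exceedance
("smokewave") episodes, population-at-risk tabulation, and a stratified
evaluation of predictions against monitor observations. A seeded synthetic
generator produces statistically realistic paired fields so the entire
pipeline is testable without any model output.

## The procedure and its assumptions

**Differencing.** `fireDifference()` computes $C_{\mathrm{fire}}$ per cell
and day. The subtraction direction is all-sources minus no-fire; that is the
only direction under which the fire share of the total is a fraction of the
all-source mean. Because transport and chemistry are nonlinear, the
difference can be slightly negative even though both runs are non-negative;
negatives are retained by default so that `fire + no_fire` reconstructs
`all_sources` exactly, and an optional `clipNegative` flag zeroes them with
a logged count. Daily values are 24-h means, midnight to midnight in local
time; `dailyFromHourly()` applies a whole-hour UTC offset and drops partial
first/last local days.

**Unit aggregation (centroid rule).** A grid cell contributes to an
administrative unit if and only if the cell's centroid lies inside the unit
polygon; the unit's daily value is the unweighted mean over its member
cells (`assignCells()`, `unitDailyMean()`). Coordinates are planar
projected values and containment uses the even-odd parity rule, so holes
are supported and ring orientation is irrelevant. Units too small to
contain any centroid are flagged empty and carried through as missing --
never as zero. Cells outside every polygon stay unassigned (model grids
extend past the study region) and are excluded from unit statistics.

**Exposure classes.** Annual unit means are pooled across units and years
and split at their 25th/50th/75th percentiles (`quartileBreaks()`), giving
four classes with lower-open, upper-closed intervals: a value exactly on a
break belongs to the class below, and 0 belongs to class 1
(`classifyExposure()`). For binning populations each unit is assigned one
class from its period-mean fire-PM2.5, while the breaks come from the
pooled unit-year values -- pooling is what makes the observed maximum of
the pooled values the printed upper bound of class 4. The California
replication configuration pins the breaks at 0.34/0.56/0.86 ug/m3 with
maximum 20.3 (`californiaBreaks()`).

**Smokewaves.** A smokewave is a maximal run of consecutive days with
fire-PM2.5 strictly above a threshold, lasting at least a minimum number of
days (`detectSmokewaves()`). The defaults encode the study definition --
the 35 ug/m3 24-h NAAQS level exceeded for more than two consecutive days,
read literally as a minimum run of 3 -- and both knobs are exposed because
related work has used runs of 2. Gaps in the date vector split runs. An
episode spanning a calendar-year boundary is counted once, in its start
year (`smokewaveCounts()`). Note one subtlety: raising the threshold can
*split* a long episode into several shorter ones, so the episode count is
not monotone in the threshold (total exceedance days are); the count is
monotone non-increasing in the minimum run length.

**Populations at risk.** Each unit's population and health-event counts are
attributed wholly to the unit's class -- the county-resolution design, with
no within-unit apportionment (`tabulateAtRisk()`). Unclassified units fall
into a Missing row, and class rows plus Missing always reproduce the Total
row. `fractionAbove()` reports the share of each variable in classes at or
above a cut, unrounded (presentation conventionally rounds population
shares to one decimal, event shares to integers). Count sources that pool
small units can be pre-processed with `allocatePooledCounts()`, which
spreads a pooled row proportionally to unit population.

**Model evaluation.** Monitors are matched to the cell containing them
under a half-open rectangle rule, so edge points resolve deterministically
(`matchMonitorToCell()`). Monitor-days are stratified by the *predicted*
fire contribution to PM2.5 carbon -- strictly above 0.34 ug/m3 is
"wildfire-impacted", at or below is "little-or-no" -- and each stratum-year
reports N, mean observed, mean predicted and the bias
`predicted - observed` (`stratumSummary()`). Pairs with a missing side are
excluded pairwise with a logged count. The converse failure mode -- smoke
present while the model predicts zero fire -- is deliberately not
evaluated, since nothing distinguishes those days in monitor data alone.

## Tunable parameters

| Parameter | Default | Units | Where | Why |
|---|---|---|---|---|
| smokewave `threshold` | 35 | ug/m3 | `smokewaveParams()` | 24-h NAAQS PM2.5 level |
| smokewave `minDays` | 3 | days | `smokewaveParams()` | "more than two consecutive days", literally |
| evaluation threshold | 0.34 | ug/m3 | `stratifyByFireImpact()` | first class break of the replication config; independent knob |
| `clipNegative` | FALSE | -- | `fireDifference()` | keep the exact run identity by default |
| percentile `type` | 7 | -- | `quartileBreaks()` | linear interpolation between order statistics |
| `sdType` | population | -- | summaries | divide-by-n; sample (n-1) available |
| `minFraction` | 0 | fraction | `annualSummary()` | no minimum-coverage rule unless requested |
| `boundaryTol` | 0 | m | `assignCells()` | exact arithmetic for the on-boundary test |

## The synthetic generator

`simulateScenario()` draws every input from a master seed, with one
deterministic stream per generator so that, e.g., adding monitors never
perturbs the fields. It emulates the *shape* of transport-model output, not
the physics:

* **Background (no-fire) field** -- `(mean + seasonal sinusoid)` times
  mean-corrected lognormal noise whose AR(1) process lives on the log
  scale. This guarantees strict positivity and temporal smoothness; the
  configured lag-1 autocorrelation is exact for the log-values (and only
  approximate for the values themselves, which is how the generator is
  tested). Cells are independent given the seasonal cycle; real fields
  carry spatial correlation the generator does not attempt.
* **Fire events** -- sparse advected isotropic Gaussian plumes with a
  trapezoidal rise-plateau-decay profile, additive across events. This is
  a stand-in producing the observed pattern of many near-zero fire days
  punctuated by sharp multi-day peaks; it is not a dispersion model.
* **Units, populations, monitors** -- a rectangular tiling of the extent
  (plus one deliberate sub-cell unit that contains no centroid, exercising
  the missing-data path), lognormal unit populations with plausible
  demographic fractions and Poisson event counts, and monitor observations
  `carbonFraction x all_sources x biasFactor(year) x mean-1 lognormal
  noise` at a 1/3/6-day cadence.

The replication configuration (`replicationScenarioConfig()`) uses 20 x 20
cells of 12 km, 7 whole years, 16 tiled units plus the sub-cell unit, and
six events per year; the event rate was calibrated once so that fire
contributes roughly a quarter of the period-mean all-source PM2.5,
mirroring the study conditions, and left alone thereafter. Passing tests on
these scenarios demonstrates the pipeline arithmetic -- attribution,
aggregation, classification, episode detection, tabulation, bias recovery
-- not fidelity to real smoke transport: real fields have spatially
correlated backgrounds, non-Gaussian plumes, and monitor error structure
richer than multiplicative lognormal noise.

## Numerical choices

* **Stored truth versus analytic plume.** The composed all-sources field is
  `background + plume` rounded to double precision, so the analytically
  injected plume is not bit-recoverable (the representable difference
  deviates from it by up to one ulp of the sum). `composeFields()`
  therefore stores as `fire_truth` the representable difference
  `all_sources - no_fire`, which is exactly what an ideal attribution of
  the composed runs can recover; `fireDifference()` reproduces it bit for
  bit, and the conservation identity `fire + no_fire == all_sources` is
  asserted exactly at scenario magnitudes.
* **Ties and degeneracy.** A centroid exactly on a shared boundary, or
  inside overlapping polygons, is assigned to the unit whose id sorts
  first lexicographically, with a warning -- deterministic and independent
  of input order. Self-intersecting rings are rejected at construction.
  Empty summaries are missing (NA), never zero. Negative annual means
  (possible without clipping) classify into class 1 with a warning.
  Identical pooled values collapse all classes into class 1.
* **Precision in files.** Field and monitor CSVs print doubles with 17
  significant digits, so write/read cycles are lossless and pipeline reruns
  are byte-identical.

## Problem sizes

The test suite runs scenarios up to 20 x 20 cells x 7 years (about one
million cell-days), 1000 random series against the brute-force episode
oracle, and a 50-monitor year (18,250 monitor-days) for bias recovery; the
whole suite completes in well under a minute on one CPU. These sizes were
chosen as the smallest at which the checked properties are informative.

## Known limitations

* No reprojection: unit polygons must already be in the grid's planar
  coordinate system, and no geodesic computation is performed.
* No dasymetric (population-weighted) cell-to-unit apportionment; the
  centroid rule is the only aggregation implemented.
* Gridded fields are exchanged as long-format CSV only.
* Speciation is reduced to a single carbon fraction applied to PM2.5; no
  ozone, no sub-daily metrics, no population mobility or averting
  behaviour.
* The at-risk tabulation is descriptive: it does not link exposure windows
  to the timing of health events.
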