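---
title: "Modelling odontocete detection patterns from duty-cycled passive acoustic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling odontocete detection patterns from duty-cycled passive acoustic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamgee)
```

## The problem

Long-term seafloor hydrophone recorders (HARPs and similar) produce, after
click detection and classification, a stream of labelled 5-minute bins: for
each echolocation click type (a species or species group of toothed whales),
the number of clicks the classifier attributed to that type in each bin.
Two features of these data frustrate naive analysis:

* **Imperfect classification.** Only a fraction of labels are true
  positives, and that fraction (the classifier's *precision*) differs by
  type and site.
* **Duty cycling.** To extend battery life, many deployments record only
  part of each cycle (e.g. 5 minutes on / 10 minutes off), so duty-cycled
  deployments systematically under-count detection minutes relative to
  continuous ones — and not equally for all species, because detections
  arrive in bouts.

pamgee implements the full chain from labelled bins to inference:

1. **Precision adjustment and thresholds.** Bin counts are multiplied by the
   (site, type) precision to approximate "true" clicks, then bins are
   retained only when the adjusted count strictly exceeds a class threshold
   — more than 50 clicks for delphinids, more than 20 for beaked whales and
   *Kogia* spp., reflecting their lower clicking rates.
2. **Hourly roll-up.** Every minute of a retained bin is credited with
   detections, giving detection minutes per hour against recorded minutes
   per hour (the effort).
3. **Duty-cycle correction.** For each site and type, the retained-bin
   series from *continuous* deployments is subsampled through each duty
   cycle used at the site, at every 5-minute phase offset; the mean fraction
   of detection minutes lost is inverted to linearly boost duty-cycled
   hours: `minutes / (1 - missed_fraction)`, capped at 60 min/h. Zeros stay
   zero — boosting never creates presence.
4. **Composition.** Percent of recording days with detections per site and
   type (the abundance proxy), seasonal changes, and Bray–Curtis similarity
   of every site against a focal site, overall and per season.
5. **Temporal models.** Hourly presence/absence is modelled with binomial
   GAM-GEEs: cyclic spline smooths of hour of day and day of year, an
   optional multi-year smooth, lunar illumination as linear or smoothed
   (chosen by QIC), temporal blocking into clusters, robust Wald term tests
   at α = 0.05, backwards QIC ordering, coefficient-bootstrap partial-fit
   curves, and binned-residual / Tjur's R² diagnostics.

## The model

The response is hourly presence: an on-effort hour scores 1 when any
detection minutes were credited. For hour \(t\) with covariates
\(x_t\),

\[\mathrm{logit}\, P(y_t = 1) = \beta_0 + f_{24}(\mathrm{hour}_t)
  + f_{365}(\mathrm{doy}_t) + f_{\mathrm{yr}}(\mathrm{year}_t)
  + g(\mathrm{lunar}_t),\]

where \(f_{24}\) and \(f_{365}\) are *cyclic* M-spline smooths (period 24 h
and one year; day of year enters as a fraction of the year's length so leap
years align), \(f_{\mathrm{yr}}\) is an open smooth offered only when a site
spans more than 5 years, and \(g\) is linear or an open smooth, whichever
has the lower QIC in a lunar-only model (ties go to linear).

**Spline basis.** Smooths use M-splines — non-negative basis functions
built from B-splines on the same knots, each integrating to one. "Four
knots" means four distinct knots including both boundaries (two interior
knots), cubic degree, and no basis intercept (the model supplies its own):
an open smooth contributes 5 free coefficients and a cyclic smooth 2. The
cyclic basis is periodic *by construction*: uniform knots are extended past
the period and translated copies one period apart are folded together, so
\(B(t) = B(t + P)\) exactly. The tests verify the basis against an
independent de Boor recursion.

**Estimation.** The GEE uses an independence working correlation, under
which the estimating equations coincide with the ordinary binomial GLM
score equations; within-cluster dependence is carried entirely by the
cluster-robust (sandwich) covariance
\(V_R = A^{-1}\left(\sum_c U_c U_c^\top\right) A^{-1}\), with \(A\) the
information matrix and \(U_c\) the cluster score sums. Both \(V_R\) and the
model-based \(A^{-1}\) are retained.

**Blocking.** Clusters are contiguous blocks of on-effort hours whose
length is the smallest lag at which the autocorrelation of deviance
residuals from a basic all-variable GLM drops below 0.1 (residual type
configurable; the search caps at 14 days with a warning). Blocks restart at
effort gaps.

**QIC.** \( \mathrm{QIC} = -2\,QL + 2\,\mathrm{tr}(\Omega_I V_R) \) with the
binomial quasilikelihood \(QL = \sum y \ln\hat\mu + (1-y)\ln(1-\hat\mu)\)
and \(\Omega_I\) the inverse model-based covariance of the independence
fit. When \(V_R\) equals the model-based covariance the penalty reduces to
\(2p\) — a tested identity.

**Selection.** Terms with robust Wald \(p \ge 0.05\) are dropped and the
model refitted iteratively until all remaining terms are significant (a
single-shot variant is available by flag). Remaining terms are ranked by
\(\Delta\mathrm{QIC}\) — the QIC increase when the term is removed and the
model refitted — largest first, ties broken by the Wald χ². Models are
attempted only for series with strictly more than 100 detection hours.

**Uncertainty.** Partial-fit curves draw `n_boot` coefficient vectors from
\(N(\hat\beta, V_R)\), evaluate the term's basis on a grid, and take
pointwise 2.5/97.5 percentiles; curves are reported both as the term's
contribution on the linear-predictor scale and on the probability scale
with other design columns at their observed means.

**Diagnostics.** Binned residuals sort observations by fitted probability
into ~√n equal-count bins and compare each bin's mean raw residual to
\(\pm 2\sqrt{\bar p(1-\bar p)/n_\mathrm{bin}}\); a well-calibrated model
keeps at least 95% of bins inside. Tjur's R² is the mean fitted probability
among presence hours minus that among absence hours.

## The synthetic-data generator

`simulateClickBins()` emulates the monitoring data the pipeline consumes,
with known ground truth for recovery testing. Per site × type:

* a **two-state bout process** on the 5-min grid with lag-1 persistence
  \(\rho\) (the probability of keeping the previous state rather than
  redrawing) and baseline occupancy \(\pi_0\);
* an **additive temporal predictor** — cosine diel and seasonal terms with
  configurable peak and amplitude, per-year multiplicative factors, and a
  lunar-illumination term applied only when the sun is below the horizon
  (illumination is behaviourally meaningful only at night; configurable) —
  that shifts *both* the log click rate while active and the log-odds of
  bout activity. Both channels matter: with realistic click rates well
  above the retention thresholds, structure placed only in the click rate
  would vanish from hourly presence, while real bout behaviour moves
  presence itself;
* **Poisson click counts** at rate `base_rate × exp(predictor)` while
  active;
* **label noise**: false-positive bins are injected at empty slots so the
  long-run fraction of labelled bins that are true equals the stated
  precision (calibrated to within 0.01 in tests);
* **duty-cycle subsampling** through each deployment's schedule.

A bout process rather than pure Poisson counts is used deliberately:
duty-cycle losses are type-specific exactly when detections cluster in
time, which is what makes site- and type-specific loss estimation
necessary in the first place. All times are local standard time UTC−10
(no daylight saving), stored as ISO-8601 with a fixed offset.

`groundTruth()` evaluates the same rate model in closed form — bin
probability `occupancy(t) × P(Poisson(λ(t)) > threshold)`, hourly
probability from an independence product over the hour's 12 bins — as the
oracle for recovery tests. Bout persistence concentrates detections and
lowers realised hourly probability below this marginal form; peak
locations and monotonicities, which the recovery tests use, are
unaffected.

**What the generator does not emulate:** propagation loss and
detection-range variation with depth or noise (range is treated as constant
per site), cue-rate differences between individuals, classifier confusion
*between* types (noise is type-independent), and diel structure in the
false positives (real boat-noise misclassifications are day-biased).
Passing recovery tests therefore demonstrate that the pipeline's
arithmetic and inference are sound under the stated generating process,
not that any particular field data set satisfies that process.

## Defaults and tunable parameters

| Parameter | Default | Why |
|---|---|---|
| bin width | 300 s | the classifier's labelling increment |
| delphinid threshold | > 50 true clicks/bin | clicking-rate-based retention rule |
| beaked/Kogia threshold | > 20 true clicks/bin | lower clicking rates |
| modelling gate | > 100 detection hours | below this, patterns are unreliable |
| knots | 4 distinct (2 interior), cubic | guards against overfitting; df 2 cyclic / 5 open |
| ACF blocking cutoff | 0.1 | residual dependence considered negligible |
| significance level α | 0.05 | term retention cutoff |
| year smooth | only if span > 5 yr | shorter spans cannot support a smooth trend |
| `n_boot` | 1000 | stable 2.5/97.5 percentile bands |
| seasons | Jan–Mar, Apr–Jun, Jul–Sep, Oct–Dec | calendar quarters |

No multiple-testing correction is applied anywhere (one Wald test per term
per model, reported as-is).

## Numerical and design choices

* **"Linearly boost"** is implemented as division by the retained fraction
  `1/(1 − missed_fraction)`, since the loss is expressed as the fraction of
  detection minutes missed and the correction must invert expected
  retention; results are capped at 60 min/h. Loss estimation averages over
  all 5-minute phase offsets of the cycle to remove alignment artifacts.
* **Order of operations**: thresholds are applied to precision-adjusted bin
  counts *before* the hourly roll-up; boosting acts on hourly minutes
  afterwards. Losses are pooled across all continuous deployments at a
  site; a site with no continuous reference for a type falls back to
  another site's loss with a logged warning.
* **Type consolidation** is a union at the 5-min bin level when bin data
  are available (a bin detected for two member types counts once), else
  `min(60, sum)` at the hourly level. Subsite merging concatenates series;
  on the (unusual) overlap, presence is the union and minutes the maximum.
  On non-overlapping grids consolidation and merging commute.
* **Bray–Curtis**: the index is reported as a similarity
  (`2Σmin/Σ(x+y)`; 1 = identical composition) with the complementary
  dissimilarity alongside; types absent at a site enter the common type
  vector as zero rather than being dropped. Per-season tables use
  season-specific recording-day denominators.
* **Weeks** are 7-day blocks from January 1, week 52 absorbing the final
  1–2 days; weekly detection hours are deliberately not normalised by
  effort, and the across-year SE is reported as 0 with a flag when only one
  year has effort.
* **ANOVA flavour**: term tests are marginal (type-III-style) Wald block
  tests on the robust covariance — one row per variable irrespective of
  order. Sequential tests would give different χ² values; the marginal
  form matches a table reporting one test per variable.
* **Ties and degenerate cases**: QIC ties in the lunar-form choice go to
  linear (parsimony); all candidate terms failing significance returns a
  flagged intercept-only model; hours straddling deployment boundaries are
  on-effort iff at least one minute was recorded; a constant covariate
  under a smooth raises an error suggesting a linear term.
* **Ephemeris**: solar altitude and lunar illuminated fraction use the
  standard low-precision geocentric series (accuracy a few tenths of a
  degree and ~0.01 illumination), verified in tests against documented
  new/full-moon dates and the 29.53-day synodic period; a user-supplied
  covariate table overrides computed values when higher precision is
  needed.
* **Determinism**: every stochastic step (generator, bootstrap) takes an
  explicit seed and restores the caller's RNG state.

## Problem sizes used in tests

The test suite and acceptance script run entirely on synthetic data at desk
scale, chosen to keep each check sharp but quick: one simulated year of
hourly data (n = 8760) for parameter recovery (50 replicates; diel peak
hour 13 with log-odds amplitude 2, seasonal peak day 180 with amplitude 2 —
the seasonal amplitude is our choice, matching the diel one); n = 5000
hours × 500 replicates for binned-residual calibration; ~10⁵ bins for
precision calibration and flat-rate uniformity; 10⁶-step AR(1) series for
the blocking-lag oracle. A full three-site, eight-type, two-year pipeline
run takes under a minute on one CPU.

## Known limitations

* The independence working correlation is the only one offered; robust
  standard errors carry the dependence, but efficiency gains from
  exchangeable or AR structures are out of scope.
* Sandwich-based Wald tests are mildly anti-conservative when clusters are
  few; the null-calibration test asserts a ≤10% rejection rate at nominal
  5% rather than a tighter bound.
* With strong, saturating detection processes the hourly presence series
  can plateau near 1, leaving little temporal signal to model — a property
  of the data, not the code.
* The year smooth extrapolates across effort gaps; conclusions about years
  with little or no data should not be drawn from it.
* No environmental covariates (e.g. chlorophyll-a, SST) and no
  collinearity machinery: the models are temporal-only by design.
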