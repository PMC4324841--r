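---
title: "Degree-day voltinism under climate scenarios: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-day voltinism under climate scenarios: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voltigen)
```

## The question

*Spodoptera litura* (tobacco caterpillar) is a defoliator of peanut across
India. Like all ectotherms its development rate is driven by temperature, so
a warmer climate lets it complete more life cycles — more generations — in
the same crop season, with correspondingly more damage potential. This
package asks the quantitative version of that question: given daily maximum
and minimum temperature series for a peanut-growing location under a future
emission scenario, how many generations does the degree-day model predict
over the crop season, how long is each generation, and how much of the
variation in those predictions is attributable to location, time period,
climate model and scenario?

## The degree-day model

Development is tracked in growing degree-days (GDD). Each day contributes

$$ DD = \max\left(0,\; \min\!\left(\frac{T_{max}+T_{min}}{2},\, T_{upper}\right) - t_0\right) $$

with a lower developmental threshold $t_0 = 10\,^\circ$C (development ceases
below it) and an upper threshold $T_{upper} = 37\,^\circ$C applied as a
*horizontal cut-off*: heat above the upper threshold does not count, so the
effective daily mean is capped before the threshold is subtracted. Two
consequences of this formulation are worth noting:

* a day's contribution is never negative (cold days contribute zero rather
  than debiting the total), and
* no day can contribute more than $T_{upper} - t_0 = 27$ DD.

The cut-off is applied to the daily *mean*. The horizontal method is defined
by its cap on accumulation above the upper threshold; with the
simple-average formula the daily mean is the only operand available to cap,
and this is the standard form of the method. (Vertical and intermediate
cut-offs, and sine-wave/hourly integration, are deliberately out of scope.)

Daily contributions are accumulated over the **crop-season window**:
standard meteorological weeks 26–44, where week $w$ covers days
$7(w-1)+1 \dots 7w$ of the year (week 1 = Jan 1–7). That window is days
176–308, i.e. 133 days — the peanut season at the study locations. Days 365
and 366 fall outside the 52-week grid; the window arithmetic is therefore
independent of leap years, and the generator's default year length is 365.
Accumulation restricted to the growing season (rather than the calendar
year) makes the predictions conservative: a warming-extended season is not
credited.

A generation requires $K = 522.7$ DD (egg to adult on peanut). With total
seasonal degree-days $TDD$:

* number of generations $N = TDD / K$, reported fractionally (a partially
  completed final generation counts pro rata; `accumulate_generations()`
  also reports the completed count and the window day on which each whole
  multiple of $K$ is first reached);
* generation time $GT = 133 / N$ days.

### Why GT divides the window

The verbal definition of generation time — "average development time per
cycle" — admits two readings: divide the window by the fractional $N$, or
average the intervals between completed-generation boundaries. We default to
the former, for an empirical reason: across the published location-level
tables the product $N \times GT$ reconstructs the 133-day window to within
2% in the overwhelming majority of cells (median deviation well under 1%),
which is the signature of the window definition. The boundary-interval
alternative is retained (`generation_time(..., definition = "boundary")`)
because it answers a subtly different question (how long did the *completed*
cycles take) and differs whenever warm and cool spells alternate within the
season.

The `mean_gdd` field (mean degree-days per completed generation) equals $K$
up to boundary-day granularity by construction; it is computed and reported
anyway because a deviation from $K$ beyond one day's accumulation signals an
accumulation bug. Tests rely on this self-check.

## The weather surrogate

The original temperature inputs were GCM projections downscaled to daily
series by a stochastic weather generator, 20 replicates per location ×
model × scenario × period cell; those daily files are not redistributable.
The package therefore generates its own replicates from a transparent
surrogate with three components:

1. **Seasonal cycle**: a cosine around the location's annual means,
   $m(d) = \bar{T} + A\cos(2\pi(d - d_{peak})/365)$, with amplitude
   $A = 4\,^\circ$C for both Tmax and Tmin and peak day 135 at all six
   locations (plausible for peninsular India; the annual mean — the
   calibrated quantity — is unaffected by either choice). The cosine grid is
   mean-centred so the annual mean closes exactly on the target.
2. **Scenario/period offset**: a constant added to every day, equal to the
   *published annual-mean difference* between that scenario × period and
   the 1975 baseline, per location and separately for Tmax and Tmin
   (`all_scenario_offsets()` derives all 108 deltas from the packaged
   annual-means table by subtraction). The baseline offset is zero.
3. **Replicate noise**: independent Gaussian noise, sd 1 °C, per day and
   per variable. Replicate $r$ of a cell uses a child seed derived
   deterministically from the cell seed and $r$, so any subset of a study
   replays exactly. The rare day on which drawn Tmin exceeds drawn Tmax is
   repaired by swapping the two values — a rejection-free rule that
   preserves both determinism and the day count.

Climate models are differentiated by a fixed multiplicative factor on the
scenario offset (BCC 0.88, CNR 1.12, CSI 1.06, ECH 1.08, INM 0.92,
MIR 0.94): the models documented as projecting warmer futures scale the
warming up, the cooler ones scale it down, and the factors average to
exactly 1 so that the ensemble (`AVG`) — computed by averaging the six
models' daily temperatures per replicate index — reproduces the published
scenario-level deltas. Averaging *weather* rather than *predictions* is the
default because the ensemble of record is an ensemble of climates; the
prediction-averaging alternative is available in `ensemble_average()` and
differs exactly when the cut-off or threshold binds for some models only (a
Jensen gap, exercised in the tests).

### What the surrogate does and does not emulate

It emulates: the factorial replicate structure; annual-mean temperatures
matching the published table exactly (in expectation; exactly at zero
noise); warming that scales across periods and scenarios; seeded
reproducibility. It does **not** emulate: rainfall-conditioned temperature
generation, within-season warming structure (the offset is uniform over the
year), inter-replicate climatology differences (our replicates share the
seasonal cycle and differ only in daily noise, so replicate SEs are much
smaller than the published ones), or spatial downscaling. Consequently
passing tests demonstrate correctness of the degree-day and statistical
machinery *given* daily temperatures, and directional/structural
plausibility of the pipeline — not numerical reproduction of the original
voltinism values, which depend on undeposited daily data. The package's
acceptance surface is built accordingly: exact checks on the published
annual-mean deltas and window arithmetic, property-based checks (loop-oracle
equivalence, closed-form closure, monotone warming response, ANOVA SS
conservation, planted-effect recovery, end-to-end determinism) on everything
else.

One structural mismatch deserves emphasis. The published annual means place
Junagadh under B1/2020 *below* its 1975 baseline (Tmax −0.82 °C, Tmin
−1.40 °C), yet the published generation counts for that cell are above
baseline — the original crop-season temperatures evidently moved differently
from the annual means. A surrogate calibrated on annual means necessarily
predicts slightly *fewer* generations than baseline there. Every other
location × scenario × period cell warms, and the direction-of-effect claims
(more generations and shorter generation times in the future periods;
very-distant future exceeding near future) hold at all of them.

## Statistics

* **Cell summaries**: mean ± SE (sd/√n) of $N$ and $GT$ over replicates; a
  single-replicate cell reports SE 0, matching the baseline convention of
  the published tables.
* **t-tests**: each future cell vs the same location/model baseline cell,
  two-sample, two-sided, equal variances assumed, df $= n_a + n_b - 2$. If
  one sample has zero variance the pooled variance reduces to the other
  sample's contribution and the result is flagged; if both do, the statistic
  is reported as undefined rather than fabricated. No multiplicity
  correction is applied; significance at p < 0.01 is exposed as a boolean.
* **Variance partition**: fixed-effects ANOVA on replicate-level responses
  with main effects location, period, model, scenario and the
  location × period interaction reported separately (the interaction the
  original analysis singles out); all other interactions remain pooled in
  the residual, reported as "others". Each source's sum of squares is
  divided by the total SS. The design is balanced by construction, where
  sequential SS are order-independent — `anova_partition()` refits with the
  source order reversed and asserts agreement rather than assuming it, and
  refuses unbalanced designs outright (no Type-II/III fallback). The
  baseline period is excluded by default (`include_baseline_in_anova`):
  the baseline is shared across scenarios, and the quantities of interest
  are departures from it. A constant response yields an explicitly
  undefined partition, not a division by zero.

## Numerical choices and degenerate inputs

* Generation boundaries use a tolerance of 1e−9 DD when testing whether a
  multiple of $K$ is reached, so closed-form constant-temperature cases land
  on the intended day rather than one day late through floating-point
  shortfall.
* Zero seasonal degree-days → $N = 0$, $GT$ undefined (`NA`), empty
  boundary set — a signalled absence, not an error.
* Seeds are mixed with an exact-in-double 31-bit linear congruential step,
  keeping every derived seed a valid `set.seed()` input and the whole study
  reproducible from one master seed.
* DSSAT-dialect weather files are written with `YYDDD` dates and one decimal
  place (the format's convention); both `YYDDD` and `YYYYDDD` are accepted
  on read, `-99` sentinels map to missing, and a row lacking Tmax or Tmin is
  dropped with a warning while Tmax < Tmin is a hard validation error.

## Problem sizes

The default study is 6 locations × 7 models (6 GCMs + ensemble) × 3
scenarios × 4 periods = 504 cells at 20 replicates of 365 days each (10,080
replicate-years); it runs in well under a minute on one core. The test suite
exercises the accumulation engine against a literal day-loop oracle on 1,000
random replicate-years, recovers planted ANOVA effect shares on the full
factorial at 20 replicates/cell within ±3 percentage points, and replays the
full study twice to assert bitwise determinism.

## Known limitations

* Annual-mean calibration cannot capture season-specific warming; see the
  Junagadh B1/2020 discussion above.
* Replicate SEs are understated relative to the published tables because
  the surrogate's replicates share one climatology.
* The published location tables themselves contain a handful of cells
  (concentrated in the 2020 rows) whose printed $N \times GT$ products
  deviate from the 133-day window by up to ~11%, far beyond rounding; the
  package reports the consistency distribution rather than forcing those
  cells to agree.
* Temperature is the only driver: rainfall, solar radiation, elevated CO₂,
  crop phenology and natural-enemy interactions are out of scope, so
  predictions are upper-bound indicators of thermal potential, not
  population forecasts.
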