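---
title: "Run chart rules and their diagnostic value"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Run chart rules and their diagnostic value}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rundx)
```

## The model behind a run chart

A run chart plots a quality measure over time with a horizontal line at the
process median. Under the null model of a stable process the observations
are independent and identically distributed, so each point falls above or
below the median with probability one half, independently of its
neighbours. A sustained change in the process level (a *shift*) breaks this
symmetry and shows up as an unusually long run of points on one side of the
median, or as unusually few crossings of the median line.

`rundx` computes the statistics this argument relies on:

* **useful observations** `n`: points not exactly on the median. On-median
  points are removed before any run counting — they neither extend a run
  nor break it.
* **runs**: maximal blocks of consecutive useful points on the same side of
  the median.
* **crossings**: adjacent useful points on opposite sides; the number of
  runs is always the number of crossings plus one.
* **longest run** and **longest trend**: the largest run, and the largest
  number of points moving strictly in one direction.

The trend statistic counts *points*, not steps, and collapses consecutive
repeated values to a single point first, so a flat stretch inside an
otherwise rising segment neither extends nor breaks the trend. When the
direction changes, the pivot point belongs to both the ascending and the
descending stretch (so `1, 5, 2` contains two 2-point stretches). The
median plays no role in the trend: it is computed on all points, including
those on the median. These conventions are one consistent reading of a
convention the field leaves underspecified (whether the pivot is shared);
sharing the pivot matches the usual "k points in the same direction"
phrasing and is fixed here once and for all.

## Signal limits

Because each of the `n - 1` adjacent pairs of useful points crosses the
median independently with probability 1/2 under the null, the number of
crossings follows `Binomial(n - 1, 1/2)`. The package derives every
dynamic limit from this model:

* **crossings lower limit** (Anhoej): the 5% quantile — the smallest `k`
  whose binomial CDF reaches 0.05. Fewer crossings than this signals.
* **longest-run upper limit** (Anhoej): `round(log2(n) + 3)`, with halves
  rounded up; a run *longer* than this signals. At `n = 24` both limits
  equal 8.
* **runs-count band** (Perla, Carey): the two-sided 5% band, i.e. the 2.5%
  and 97.5% crossing quantiles converted to runs via runs = crossings + 1.
  Run counts outside the band signal. Classical run-count tables built
  directly on the permutation distribution of runs give comparable values;
  the binomial route may differ by ±1 at some `n`, which is accepted here
  for its simplicity and is covered by calibration tests (the runs test
  alone fires at roughly its nominal 5% on random charts).

## The three rule sets

| test | Anhoej | Perla | Carey |
|---|---|---|---|
| longest run | > UPL | ≥ 6 | > 7 (> 8 with ≥ 20 useful obs.) |
| runs / crossings | crossings < LPL | runs outside band | runs outside band |
| longest trend | — | ≥ 5 | > 6 |

A rule set signals when *any* of its component tests is positive. A chart
with no useful observations (every point on the median, possible with
count data) is reported as not evaluable rather than as a non-signal of
substance; in simulations such charts count as no-signal and are tallied
separately.

**Why Carey's thresholds are exclusive here.** Published statements of the
Carey rules are ambiguous at the boundary: the same sources that tabulate
the thresholds as "7 or more / trend of 6 or more" also work examples in
which a chart with a longest trend of exactly 6 shows *only random
variation* under Carey. The two readings are distinguishable by their
operating characteristics, and only the exclusive reading reproduces the
published error rates: with inclusive thresholds the Carey false-signal
rate on 24-point random charts is about 15–16%, roughly half again the
published ~10%, and Carey's sensitivity to a 2 SD shift exceeds Anhoej's
by 2–3 points where the published tables show them equal (their shift
tests coincide at 24 points only under the exclusive reading). `rundx`
therefore implements Carey with strict comparisons — a run signals when it
*exceeds* 7 (8 from 20 useful observations), a trend when it *exceeds* 6 —
and Perla with inclusive ones (≥ 6, ≥ 5), which is the combination
consistent with both the worked examples and the published contingency
tables. The unit tests pin this boundary behaviour explicitly.

## The simulation study

`run_simulation_grid()` reproduces the reference evaluation design:

* baselines of 6, 12 or 18 points fix the median; post-baseline periods of
  6, 12 or 18 points follow — a 3 × 3 grid;
* in the shifted arm the post-baseline mean moves up by `shift_sd = 2`
  standard deviations; the unshifted arm is pure noise;
* 1000 replicates per arm and condition: 18,000 charts for the default
  grid;
* every chart is scored by *all* rule sets (a paired design, so
  between-rule comparisons carry no generation noise);
* per-condition RNG substreams are derived deterministically from the root
  seed, so any subset of conditions reproduces exactly the charts of the
  full grid.

Normal data are drawn from N(0, 1), making a "2 SD shift" literally +2.
Nothing is lost by this: every statistic depends only on orderings and
equalities, so the rules are invariant to location and scale. The Poisson
option draws from mean `lambda` (default 16) and shifts the post-baseline
mean to `lambda + shift_sd * sqrt(lambda)`; λ = 16 keeps the skewness mild
and the shifted mean at the integer 24. The reference study reports only
that count data behaved comparably, without parameters, so the Poisson arm
is exercised by property tests rather than by acceptance checks.

Sensitivity, specificity and the likelihood ratios LR+ =
sens/(1 − spec) and LR− = (1 − sens)/spec are computed from the raw 2 × 2
counts by `diagnose()`. No continuity correction is applied: a perfect
test reports `LR+ = Inf` and `LR− = 0` as such, and the counts are kept in
every result so downstream code never loses precision to rounding.

## Numerical choices

* **Median ties.** Values and the median are compared after rounding both
  to 10 decimal places. Floating-point noise therefore cannot make a
  genuine median hit look like a useful observation, while integer data
  (counts with an integer median) tie exactly. With an even baseline on
  continuous data no point ties the median, so a 12-baseline/12-post chart
  always has 24 useful observations.
* **Degenerate inputs.** An empty or all-on-median series yields zero run
  statistics rather than an error, and every rule set reports
  `evaluable = FALSE`; `longest_trend()` returns 0 for an empty series and
  1 for a single point.
* **Boundaries.** All Anhoej comparisons are strict (a chart sitting
  exactly on a limit does not signal), matching the limits' definition as
  prediction limits for ordinary behaviour.

## What a green test does and does not establish

The generator emulates a stable process with a single, sustained,
instantaneous shift at a known point. Real quality measures also exhibit
drifts, transient shifts, autocorrelation, seasonal structure, and
medians recomputed as data accrue — none of which are simulated, and the
reported sensitivities and specificities do not transfer to those
settings. The simulation measures the rules' operating characteristics
under the stated world only; it ranks rule sets under identical
conditions rather than establishing fixed diagnostic properties.

## Limitations

* The runs-count band is a binomial approximation to the permutation
  distribution of run counts; at some chart lengths it differs by one
  from classical tables.
* Trend conventions differ between publications; charts whose verdict
  hinges on a trend of exactly the threshold length should be read with
  that in mind (the package documents its boundary choices above).
* Likelihood ratios from 1000-replicate arms carry Monte-Carlo noise of
  roughly ±10% near LR+ ≈ 10; rerunning with another seed moves the
  third significant figure, not the conclusion.
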