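# rundx

Run chart analysis for quality-measure time series, and a Monte-Carlo
framework for scoring run chart *rule sets* as diagnostic tests.

Run charts — line graphs of a measure over time with the median as centre
line — are the workhorse of healthcare quality improvement: infection
rates, waiting times, readmissions, adherence to procedures. Improvement
(or degradation) appears as non-random patterns around the median, and
several incompatible sets of decision rules are in circulation for calling
such patterns. `rundx` is for analysts who need to (a) apply those rules
to their own series and (b) understand what each rule set's verdict is
actually worth.

## The statistics and the rules

For a series with median $m$ (computed from a fixed baseline segment and
held constant), let $n$ be the number of *useful* observations (points
$\neq m$; points on the median are dropped and neither extend nor break a
run). Under a stable process each useful point is above or below $m$
independently with probability 1/2, so the number of median *crossings*
$C \sim \mathrm{Binomial}(n-1, 1/2)$ and the number of runs is $C + 1$.

Three published rule sets are implemented:

* **Anhoej** — longest run $> \mathrm{round}(\log_2 n + 3)$, or
  $C <$ the 5% quantile of $\mathrm{Binomial}(n-1, 1/2)$;
* **Perla** — longest run $\geq 6$, runs count outside the two-sided 5%
  band, or longest trend $\geq 5$ points;
* **Carey** — longest run $> 7$ ($> 8$ with $\geq 20$ useful
  observations), runs count outside the band, or longest trend $> 6$
  points (see the vignette for why Carey's thresholds are exclusive).

A rule set signals when any component test fires. The simulation module
generates charts with a known truth — baseline of 6/12/18 points fixing
the median, post-baseline of 6/12/18 points with or without a sustained
shift of 2 SD in the mean — and scores each rule set by sensitivity,
specificity and likelihood ratios
$LR+ = \mathrm{sens}/(1-\mathrm{spec})$,
$LR- = (1-\mathrm{sens})/\mathrm{spec}$.

## Worked example

Analysing a monthly count series (28 points, median from the first 12):

```r
library(rundx)
set.seed(8)
df <- data.frame(date = 1:28, value = round(rnorm(28, 20, 4)))
analyze_series(df, baseline = 12)
#> Run chart analysis
#>   points: 28  baseline: 12  median: 18.5
#>   useful: 28  crossings: 12  runs: 13  longest run: 6  longest trend: 5
#>   limits: longest-run UPL 8, crossings LPL 9, runs band [9, 20]
#>   anhoej : random variation
#>   perla  : SIGNAL (shift, trend)
#>   carey  : random variation
```

All 28 points are useful (none hit the median 18.5). The longest run (6)
does not exceed the Anhoej limit (8) and 12 crossings is not below the
lower limit (9), so Anhoej — and likewise Carey — sees only random
variation in what is, by construction, pure noise. Perla signals anyway:
a run of 6 and a trend of 5 points both cross its laxer thresholds,
illustrating its propensity for false alarms. `tidy()` on the result
returns the per-test verdicts as a tibble; `report_json()` writes the
same numbers as JSON.

Scoring the rule sets on the 12-baseline/12-post condition (1000
simulated charts per arm, 2 SD shift):

```r
sim <- run_simulation_grid(sim_conditions(12, 12, n_reps = 1000), seed = 1)
dplyr::select(tibble::as_tibble(sim), rule_set, tp:fn, sensitivity:lr_neg)
#> # A tibble: 3 × 9
#>   rule_set    tp    fp    tn    fn sensitivity specificity lr_pos lr_neg
#>   <chr>    <int> <int> <int> <int>       <dbl>       <dbl>  <dbl>  <dbl>
#> 1 anhoej     872    83   917   128       0.872       0.917  10.5  0.140
#> 2 perla      986   455   545    14       0.986       0.545   2.17 0.0257
#> 3 carey      860    84   916   140       0.86        0.916  10.2  0.153
```

A positive Anhoej or Carey signal makes a true 2 SD shift about ten times
more likely than not (LR+ ≈ 10); a positive Perla signal barely doubles
the odds (LR+ ≈ 2.2), though its negative verdict is excellent at ruling
a shift out (LR− ≈ 0.03). `run_simulation_grid(sim_conditions(), seed = ...)`
runs the full 3 × 3 grid (18,000 charts); `plot_likelihood_ratios()`
draws the LR panels and `write_simulation_results()` exports the
contingency and diagnostics tables as CSV.

A command-line front-end with `analyze` and `simulate` subcommands lives
at `inst/cli/runchart.R`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline numbers from
scratch: it simulates the 12:12 condition with 1000 charts per arm at the
given seed, scores all three rule sets, and reports their sensitivity,
specificity and likelihood ratios together with the closed-form Anhoej
longest-run limit at 24 useful observations, as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
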