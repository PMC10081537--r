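# nof1seq

Serial correlation and sequential designs for personalized (N-of-1) trials.

A personalized trial alternates one individual between an intervention and a
comparator and compares serial response measurements across periods. Densely
sampled single-subject series are serially correlated — typically well
described by an AR(1) process $X_t = \phi X_{t-1} + e_t$ with lag-$k$
autocorrelation $\phi^k$ — and analyses that ignore this, especially when
washout intervals separate the treatment periods, mistake chance local
excursions of the series for intervention effects. `nof1seq` is a simulation
and inference toolkit for exactly this setting. It provides:

* **AR(1) simulation and diagnostics** — exactly stationary
  unit-marginal-variance series (`simulate_ar1()`), rolling means with
  $\pm 2\,\mathrm{SE}$ bands (`rolling_band()`).
* **Crossover designs** — `2 × periods × measures` designs with washouts and
  optional period-order randomization; trials carved from continuous series
  at random start positions (`design_spec()`, `build_sequence()`,
  `assemble_trial()`).
* **Intervention-effect tests** — naive OLS on the arm dummy
  (`ols_dummy_test()`), profile-ML AR(1) generalized least squares with
  either gap-ignoring or true-time correlation across washouts
  (`gls_ar1_test()`), and Newey-West HAC-robust OLS (`newey_west_test()`).
* **Sweep harness** — seeded false-positive-rate and power sweeps over
  $\phi$ grids and designs (`fpr_sweep()`, `power_sweep()`), and
  `reproduce()` to re-run each canonical study at full or reduced scale with
  CSV + manifest output.
* **Truncated SPRT for aggregated trials** — Wald sequential probability
  ratio machinery for binary outcomes (`wald_boundaries()`,
  `run_truncated_sprt()`) and the sequential aggregation of individually
  analyzed personalized trials into a population response-rate decision
  (`simulate_aggregated()`).
* **Bootstrap-calibrated slope SPRT** — quickest single-subject detection of
  a regression slope with nuisance parameters (intercept, residual sd),
  where Wald boundaries must be crossed by a bootstrap percentile band of
  the statistic (parameters frozen at observed-data estimates) rather than
  by the noisy point statistic itself (`run_bsprt()`,
  `simulate_table1()`).

## Worked example

How badly does ignoring serial correlation hurt a washout design, and how
does the robust test compare?

```r
library(nof1seq)

designs <- list(no_washout = design_spec(periods = 8, measures = 5),
                washout    = design_spec(periods = 8, measures = 5, washout = 5))
fpr_sweep(c(0, 0.5), designs, reps = 1000, seed = 1)
#>   phi     design test positive_fraction reps
#> 1 0.0 no_washout  ols             0.046 1000
#> 2 0.5 no_washout  ols             0.123 1000
#> 3 0.0    washout  ols             0.056 1000
#> 4 0.5    washout  ols             0.177 1000
```

At $\phi = 0.5$ the naive OLS test rejects a true null 12% of the time even
without washouts, and 18% of the time — more than three times its nominal
5% level — when washouts separate the eight treatment periods; at
$\phi = 0$ both designs hold their level.

For the sequential slope test, a series rising at the hypothesized H2 slope
(0.05 per measurement, unit noise) is decided long before the 100-measurement
budget:

```r
y <- 0.05 * (1:100) + simulate_ar1(100, phi = 0, seed = 7)
run_bsprt(y, b1 = 0, b2 = 0.05, seed = 8)
#> Bootstrap-calibrated slope SPRT (H1: b = 0, H2: b = 0.05): accept_H2 at n = 56
#>   final statistic 16.640; OLS slope 0.0463; residual lag-1 cor 0.129
```

The naive point statistic crosses the upper Wald boundary at n = 28 on this
series; the bootstrap band waits until the crossing clears the statistic's
own resampling noise. That delay is what keeps the false-decision rates
near their nominal values when the true slope is null.

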