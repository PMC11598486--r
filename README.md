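# tremorcast

Forecasting and suppression of physiological hand tremor for
high-precision teleoperation.

Every healthy hand carries a low-amplitude, roughly rhythmic tremor
(conventionally ~8–12 Hz) superimposed on voluntary motion. When a human
operator steers a teleoperated or surgical robot, that tremor rides on the
command signal and destroys sub-millimetre accuracy. `tremorcast` implements
a decompose–tune–forecast–cancel pipeline for this problem:

- **Signal model.** The measured signal is `a(k) = e(k) + t(k)`: desired
  motion plus tremor. If the tremor one step ahead is predicted as `t'(k)`,
  the suppression model `e'(k) = a(k) − t'(k)` recovers the desired motion;
  the recovery error equals the tremor prediction error, sample by sample.
- **EEMD** (`emd()`, `eemd()`): ensemble empirical mode decomposition splits
  the non-stationary tremor into intrinsic mode functions (IMFs) and a
  residual — simple oscillatory sequences that are far easier to forecast
  than the raw signal.
- **LSTM forecasting** (`build_windows()`, `lstm_spec()`, `fit_lstm()`): one
  peephole LSTM per mode predicts the next value from a sliding window of 12
  past values (full-batch Adam training, compiled backpropagation through
  time, seed-deterministic).
- **Improved whale optimization** (`search_space()`, `iwoa_minimize()`): a
  bounded continuous minimizer — canonical WOA plus quasi-opposition
  initialization, the printed convergence-factor schedule, an adaptive
  cosine attractor weight, and greedy Gaussian elite mutation — tunes each
  forecaster's epochs, hidden units, learning rate and L2 weight against
  validation MSE.
- **Pipeline and baselines** (`pipeline_config()`, `run_comparison()`,
  `suppress_tremor()`): end-to-end orchestration with a 70/30 chronological
  split, scored by R², MAE, MSE and SMAPE against plain LSTM, untuned
  EEMD-LSTM and ARMA baselines.
- **Synthetic truth** (`simulate_tremor()`): a seedable generator of
  band-limited, amplitude-modulated tremor over smooth desired motion with
  known ground-truth decomposition, emulating the study conditions.

All user-facing functions take and return tibbles where the data is
tabular, chain with the pipe, and have `autoplot()`/`tidy()`/`glance()`
methods.

## Worked example

```r
library(tremorcast)

# Simulated 3-axis hand signal: 960 samples at 100 Hz, tremor in 6-14 Hz
truth <- simulate_tremor(n = 960, dt = 0.01, tremor_band = c(6, 14), seed = 11)

# Decompose one axis's tremor into modes
dec <- eemd(truth$tremor[truth$axis == "x"], ensemble_size = 30, seed = 11)
dec
#> <imf_decomposition> 960 samples, 8 IMF(s) + residual [EEMD: ensemble 30, noise sd 0.08322]

# Tune-and-compare at a desk-scale configuration (one axis, a couple of
# minutes on one core)
config <- pipeline_config(
  ensemble_size = 30, max_imfs = 6, iwoa_n = 6, iwoa_max_t = 10,
  bounds = forecaster_search_space(epochs = c(10, 60), hidden_units = c(4, 24),
                                   learning_rate = c(1e-3, 3e-2),
                                   l2_lambda = c(1e-8, 1e-3)),
  seed = 11)
cmp <- run_comparison(truth, config, models = c("lstm", "eemd_iwoa_lstm"),
                      axes = "x")
tidy(cmp)
#> # A tibble: 4 x 8
#>   model          axis  target        n    mae     mse   smape    r2
#>   <chr>          <chr> <chr>     <int>  <dbl>   <dbl>   <dbl> <dbl>
#> 1 lstm           x     tremor      288 0.0755 0.00880 -0.228  0.937
#> 2 lstm           x     recovered   288 0.0755 0.00880  0.0754 0.995
#> 3 eemd_iwoa_lstm x     tremor      288 0.0508 0.00411  0.0791 0.970
#> 4 eemd_iwoa_lstm x     recovered   288 0.0508 0.00411  0.0892 0.998
```

Reading the table: on the held-out 30% of the series, the tuned
decomposition pipeline (`eemd_iwoa_lstm`) predicts the tremor with R² 0.97
and less than half the plain LSTM's squared error; the `recovered` rows
score the cancelled signal `a − t'` against the true desired motion (same
MAE/MSE by algebra, different R² denominator). SMAPE uses the signed
pairwise-mean denominator as printed in the formula, which makes it erratic
for zero-mean tremor — R² and MSE are the metrics of record.

The tremor forecast can then cancel the measured signal:

```r
pred <- cmp$predictions[cmp$predictions$model == "eemd_iwoa_lstm", ]
sub <- truth[truth$axis == "x", ][pred$index, ]
sup <- suppress_tremor(sub$actual, pred$predicted, true_desired = sub$desired)
mse(sup$recovered, sup$desired)
#> [1] 0.004108804
```

A command-line interface wrapping the same functions ships in
`inst/cli/tremorcast` (subcommands `simulate`, `decompose`, `optimize`,
`compare`, `suppress`, `rerun`; every run writes a manifest JSON that
reproduces it bit for bit).

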