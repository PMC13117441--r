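# cgmforecast

Personalised short-horizon blood-glucose forecasting from continuous glucose
monitoring (CGM) data, built around four *interdependent learning frameworks*
that share one deployable forecaster:

- **IL** — independent learning: a sequence-to-sequence multilayer perceptron
  (the *primary regressor*) maps a history window `Hx` of `n` five-minute CGM
  samples to the prediction-horizon sequence `PHx` of `m` samples, trained on
  the predictive loss `LP = E(PR(Hx), PHx)` with `E` the mean squared error.
- **AL** — adversarial learning: a 1-D convolutional *auxiliary discriminator*
  `AD` scores full `(Hx, PH, post-PH)` sequences and is trained with binary
  cross-entropy to label real sequences 0 and sequences containing a predicted
  horizon 1; the regressor simultaneously minimises
  `LS = LP + LA`, where the adversarial term `LA` rewards predictions the
  discriminator scores as real.
- **CL** — collaborative learning: an *auxiliary regressor* `AR` forecasts the
  post-horizon window `PPHx` (equal in length to the horizon) from the history
  concatenated with the predicted horizon, `LC = E(AR(Hx + PHx^), PPHx)`, and
  the system minimises `LS = LP + LC`. Because `LC` is backpropagated *through
  the predicted horizon* into the primary regressor, horizon predictions are
  shaped to stay informative about what happens immediately afterwards.
- **ACL** — adversarial-collaborative learning: both auxiliaries at once,
  `LS = LP + LA + LC`, all components trained jointly with unweighted terms.

Deployment always uses the primary regressor alone; the auxiliaries exist
only to shape its training.

The package also provides everything around the frameworks: an Ohio-style CGM
simulator (5-min sampling, 40–400 mg/dL, meal excursions, sensor gaps),
Ohio-style XML and CSV I/O, leak-free imputation (interpolation on the
training side, causal extrapolation on the test side), rolling-window
reframing, mathematical evaluation (RMSE, MAE, MAPE, r²), clinical evaluation
(surveillance-error banding, adverse-event Matthews correlation), and
nonparametric model comparison (Friedman test, Nemenyi post hoc with
Holm-adjusted decisions, critical-difference diagrams).

Intended users: researchers in glucose forecasting / diabetes technology who
want a self-contained, reproducible implementation of collaborative
adversarial training for CGM series, and a statistics pipeline for comparing
forecasting systems across subjects, horizons and metrics.

## Worked example

```r
library(cgmforecast)

# simulate a two-week subject, hold out the final 3 days
profile <- cgm_profile_params(duration_days = 14, missing_rate = 0, seed = 11)
parts   <- split_train_test(generate_cgm_series(profile), test_days = 3)

# 60-min history -> 30-min horizon windows, with post-horizon targets for training
train <- reframe(parts$train, window_config(history_len = 12, ph_len = 6, include_post = TRUE))
test  <- reframe(parts$test,  window_config(12, 6, include_post = FALSE))
scl   <- fit_scaler(train)            # min-max to [0,1] (all-ReLU networks)

sys  <- train_system(apply_scaler(train, scl),
                     training_config("ACL", epochs = 100, seed = 101))
pred <- apply_scaler(predict(sys, apply_scaler(test$histories, scl)), scl, inverse = TRUE)

evaluate_forecasts(test$ph_targets, pred)$rmse
#> [1] 15.97088
evaluate_forecasts(test$ph_targets, naive_forecast(test$histories, 6))$rmse
#> [1] 18.8502
```

The two numbers are horizon-endpoint RMSEs in mg/dL on the held-out days: the
ACL-trained regressor (16.0) beats the naive persistence baseline that
repeats the last observed value (18.8). `evaluate_forecasts()` also returns
MAE, MAPE, r², the adverse-event MCC, the percentage of predictions with no
clinical risk (surveillance error < 0.5) and the average surveillance error.

Comparing frameworks across scenarios uses the rank machinery:

```r
res <- ohio_benchmark_results()               # packaged benchmark summary
res$scenario <- paste(res$dataset, res$scenario)
rm  <- build_rank_matrix(res)                 # 168 blocks = 24 scenarios x 7 metrics
round(average_ranks(rm), 2)
#>   IL   AL   CL  ACL
#> 3.06 2.51 2.25 2.18
friedman_test(rm)$p_value < 0.05
#> [1] TRUE
nem <- nemenyi_posthoc(rm)
plot_cd_diagram(cd_diagram_data(nem$mean_ranks, nem$critical_difference))
```

A thin command-line wrapper ships in `inst/cli/cgmforecast` with verbs
`simulate`, `train`, `evaluate`, `compare` and `run-all`.

## Limitations

The simulator produces plausible CGM structure (circadian rhythm, meal
excursions, trending sensor noise, contiguous gaps) but is not a
physiological glucose–insulin model, and the training frameworks are
univariate by design. See the methods vignette
(`vignettes/collaborative-adversarial-forecasting.Rmd`) for the model
assumptions, numerical choices and known limitations.
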