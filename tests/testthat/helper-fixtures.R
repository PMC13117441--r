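# shared fixture builders; everything is generated in code at test time

grid_times <- function(n, start = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  start + 300 * (seq_len(n) - 1L)
}

make_series <- function(glucose, observed = !is.na(glucose)) {
  cgm_series(grid_times(length(glucose)), glucose, observed)
}

# small fully observed smooth series for windowing tests
make_smooth_series <- function(n = 60) {
  make_series(150 + 50 * sin(2 * pi * seq_len(n) / 48))
}

# a small scaled training set and matching test set, cached per session
small_training_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- cgm_profile_params(duration_days = 3, missing_rate = 0, seed = 404)
      parts <- split_train_test(generate_cgm_series(p), 1)
      dtr <- reframe(parts$train, window_config(12, 6, include_post = TRUE))
      dte <- reframe(parts$test, window_config(12, 6, include_post = FALSE))
      scl <- fit_scaler(dtr)
      cache <<- list(
        train = apply_scaler(dtr, scl),
        test = dte,
        scaler = scl
      )
    }
    cache
  }
})
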