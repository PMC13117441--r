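#' Impute missing training values by linear interpolation
#'
#' Interior gaps are filled with straight lines between the flanking observed
#' values. Interpolation looks at both sides of a gap, which is acceptable on
#' the training side only; use [impute_testing_series()] for held-out data to
#' avoid information leakage.
#'
#' @param series a [cgm_series()] whose first and last samples are observed.
#' @return A fully observed [cgm_series()]; observed values are unchanged.
#' @export
impute_training_series <- function(series) {
  stopifnot(inherits(series, "cgm_series"))
  n <- nrow(series)
  if (n == 0L) return(series)
  if (!series$observed[1] || !series$observed[n]) {
    stop("first and last samples must be observed; trim leading/trailing gaps first",
      call. = FALSE
    )
  }
  if (all(series$observed)) return(series)
  obs <- which(series$observed)
  filled <- stats::approx(
    x = obs, y = series$glucose[obs], xout = seq_len(n), method = "linear"
  )$y
  cgm_series(series$time, filled)
}

#' Impute missing testing values by causal linear extrapolation
#'
#' Each unobserved sample is filled by extending the straight line through the
#' two most recent (observed or previously imputed) samples, then clipping to
#' the 40--400 mg/dL sensor range. No future value is ever consulted, so the
#' imputation is leak-free and suitable for held-out test data and real-time
#' use.
#'
#' @param series a [cgm_series()] with at least 2 samples before its first gap.
#' @return A fully observed [cgm_series()]; observed values are unchanged.
#' @export
impute_testing_series <- function(series) {
  stopifnot(inherits(series, "cgm_series"))
  n <- nrow(series)
  if (n == 0L || all(series$observed)) return(series)
  first_gap <- which(!series$observed)[1]
  if (first_gap <= 2L) {
    stop("at least 2 observed samples are required before the first gap",
      call. = FALSE
    )
  }
  x <- series$glucose
  for (i in which(!series$observed)) {
    x[i] <- min(400, max(40, 2 * x[i - 1L] - x[i - 2L]))
  }
  cgm_series(series$time, x)
}

#' Sliding-window configuration
#'
#' @param history_len number of history samples `n` fed to the regressor
#'   (default 12 samples = 60 min).
#' @param ph_len number of prediction-horizon samples `m` (6 for a 30-min
#'   horizon, 12 for 60 min).
#' @param include_post if `TRUE`, each sample also carries the post-horizon
#'   segment of length `m` that immediately follows the prediction horizon
#'   (needed to train the AL/CL/ACL frameworks).
#' @param stride step between consecutive window starts (default 1, the
#'   densest rolling window).
#' @return A list of class `window_config`.
#' @export
window_config <- function(history_len = 12L, ph_len = 6L, include_post = TRUE,
                          stride = 1L) {
  history_len <- as.integer(history_len)
  ph_len <- as.integer(ph_len)
  stride <- as.integer(stride)
  if (history_len < 2L) stop("history_len must be >= 2", call. = FALSE)
  if (ph_len < 1L) stop("ph_len must be >= 1", call. = FALSE)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  structure(
    list(
      history_len = history_len, ph_len = ph_len,
      include_post = isTRUE(include_post), stride = stride
    ),
    class = "window_config"
  )
}

#' Convert a prediction horizon in minutes to output steps
#'
#' @param ph_minutes horizon in minutes; must be a positive multiple of the
#'   5-minute sampling interval (30 min -> 6 steps, 60 min -> 12 steps).
#' @return Integer number of 5-minute steps.
#' @export
ph_steps <- function(ph_minutes) {
  if (any(ph_minutes <= 0) || any(ph_minutes %% 5 != 0)) {
    stop("prediction horizon must be a positive multiple of 5 minutes", call. = FALSE)
  }
  as.integer(ph_minutes / 5)
}

#' Reframe a CGM series into supervised windows
#'
#' Rolls a window of length `n + m` (+ `m` when `include_post`) over the fully
#' imputed series and splits each placement into a history row, a
#' prediction-horizon target row and (optionally) a post-horizon target row.
#' The number of windows is `floor((L - n - m - post*m) / stride) + 1`.
#'
#' @param series a fully observed [cgm_series()].
#' @param cfg a [window_config()].
#' @return A `windowed_dataset`: list with matrices `histories` (N x n),
#'   `ph_targets` (N x m), `post_targets` (N x m or `NULL`), the config and
#'   the start index of every window in the source series.
#' @export
reframe <- function(series, cfg) {
  stopifnot(inherits(series, "cgm_series"), inherits(cfg, "window_config"))
  if (!all(series$observed)) {
    stop("series must be fully imputed before reframing", call. = FALSE)
  }
  n <- cfg$history_len
  m <- cfg$ph_len
  total <- n + m + if (cfg$include_post) m else 0L
  L <- nrow(series)
  if (L < total) {
    stop(sprintf("series too short to form a single window (%d < %d samples)", L, total),
      call. = FALSE
    )
  }
  starts <- seq.int(1L, L - total + 1L, by = cfg$stride)
  x <- series$glucose
  slice <- function(offset, width) {
    idx <- outer(starts, offset + seq_len(width) - 1L, `+`)
    matrix(x[idx], nrow = length(starts), ncol = width)
  }
  structure(
    list(
      histories = slice(0L, n),
      ph_targets = slice(n, m),
      post_targets = if (cfg$include_post) slice(n + m, m) else NULL,
      config = cfg,
      starts = starts
    ),
    class = "windowed_dataset"
  )
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf(
    "<windowed_dataset> %d samples: history %d + PH %d%s (stride %d)\n",
    nrow(x$histories), x$config$history_len, x$config$ph_len,
    if (!is.null(x$post_targets)) sprintf(" + post-PH %d", x$config$ph_len) else "",
    x$config$stride
  ))
  invisible(x)
}

#' Number of samples in a windowed dataset
#' @param ds a `windowed_dataset`.
#' @return Integer sample count.
#' @export
n_windows <- function(ds) nrow(ds$histories)

#' Fit a value scaler on training windows
#'
#' The default min-max scaler maps the training value range onto [0, 1]. All
#' regressor layers use ReLU activations and therefore emit non-negative
#' values only, so targets must be scaled into the non-negative unit range;
#' min-max is the natural choice. The transform is affine and is not clamped:
#' test values outside the training range map outside [0, 1].
#'
#' @param train a `windowed_dataset` built from training data only.
#' @param method `"minmax"` (to [0,1]) or `"zscore"` (mean 0, sd 1).
#' @return A `value_scaler` object.
#' @export
fit_scaler <- function(train, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  stopifnot(inherits(train, "windowed_dataset"))
  vals <- c(train$histories, train$ph_targets, train$post_targets)
  if (method == "minmax") {
    lo <- min(vals)
    hi <- max(vals)
    if (hi <= lo) stop("degenerate training range: all values equal", call. = FALSE)
    par <- c(center = lo, scale = hi - lo)
  } else {
    par <- c(center = mean(vals), scale = stats::sd(vals))
  }
  structure(list(method = method, center = par[["center"]], scale = par[["scale"]]),
    class = "value_scaler"
  )
}

#' Apply (or invert) a fitted scaler
#'
#' @param values numeric vector/matrix, or a `windowed_dataset` (all segments
#'   are transformed).
#' @param scaler a `value_scaler` from [fit_scaler()].
#' @param inverse if `TRUE`, map scaled values back to mg/dL.
#' @return Object of the same shape as `values`.
#' @export
apply_scaler <- function(values, scaler, inverse = FALSE) {
  stopifnot(inherits(scaler, "value_scaler"))
  tf <- function(x) {
    if (inverse) x * scaler$scale + scaler$center else (x - scaler$center) / scaler$scale
  }
  if (inherits(values, "windowed_dataset")) {
    values$histories <- tf(values$histories)
    values$ph_targets <- tf(values$ph_targets)
    if (!is.null(values$post_targets)) values$post_targets <- tf(values$post_targets)
    values
  } else {
    tf(values)
  }
}
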