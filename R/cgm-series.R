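#' CGM series objects
#'
#' A `cgm_series` is a data frame with one row per 5-minute grid sample and
#' three columns: `time` (POSIXct, UTC), `glucose` (mg/dL, `NA` where the
#' sensor value is unobserved) and `observed` (logical). Timestamps are
#' strictly increasing with constant 5-minute spacing; observed glucose values
#' lie in the sensor reporting range 40--400 mg/dL.
#'
#' @param time POSIXct vector, strictly increasing, 5-min spacing.
#' @param glucose numeric vector of glucose values in mg/dL (`NA` allowed only
#'   where `observed` is `FALSE`).
#' @param observed logical vector flagging which samples carry a sensor value.
#' @return An object of class `cgm_series`.
#' @export
cgm_series <- function(time, glucose, observed = !is.na(glucose)) {
  if (length(glucose) != length(time) || length(observed) != length(time)) {
    stop("time, glucose and observed must have equal length", call. = FALSE)
  }
  if (length(time) > 1L) {
    dt <- diff(as.numeric(time))
    if (any(dt <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
    if (any(abs(dt - 300) > 1e-6)) {
      stop("timestamps must lie on a regular 5-minute grid", call. = FALSE)
    }
  }
  glucose[!observed] <- NA_real_
  obs_vals <- glucose[observed]
  if (any(is.na(obs_vals))) stop("observed samples must carry a glucose value", call. = FALSE)
  if (length(obs_vals) && (min(obs_vals) < 40 - 1e-9 || max(obs_vals) > 400 + 1e-9)) {
    stop("observed glucose values must lie in [40, 400] mg/dL", call. = FALSE)
  }
  structure(
    data.frame(time = time, glucose = glucose, observed = as.logical(observed)),
    class = c("cgm_series", "data.frame")
  )
}

#' @export
print.cgm_series <- function(x, ...) {
  n <- nrow(x)
  miss <- if (n) mean(!x$observed) else 0
  cat(sprintf(
    "<cgm_series> %d samples (%.1f days), %.1f%% unobserved\n",
    n, n / 288, 100 * miss
  ))
  if (n) {
    rng <- range(x$glucose[x$observed])
    cat(sprintf(
      "  %s .. %s | observed glucose %.0f-%.0f mg/dL\n",
      format(x$time[1], "%Y-%m-%d %H:%M"), format(x$time[n], "%Y-%m-%d %H:%M"),
      rng[1], rng[2]
    ))
  }
  invisible(x)
}

# Samples per day at the 5-minute CGM sampling interval.
SAMPLES_PER_DAY <- 288L

#' Simulation parameters for an Ohio-like CGM subject
#'
#' Bundles the statistical knobs of the CGM simulator. Defaults emulate the
#' summary statistics of the Ohio T1D benchmark cohorts: subject means around
#' 135--215 mg/dL, standard deviations around 45--70 mg/dL, values clipped to
#' the 40--400 mg/dL sensor range, and both hypoglycaemic (<70 mg/dL) and
#' hyperglycaemic (>180 mg/dL) excursions over an eight-week recording.
#'
#' @param baseline_mean mean of the slow-varying basal glucose level (mg/dL).
#' @param baseline_sd standard deviation of the day-scale basal drift (mg/dL).
#' @param circadian_amplitude amplitude of the sinusoidal circadian component (mg/dL).
#' @param meal_rate expected number of meal-like excursions per day.
#' @param meal_amplitude_range length-2 numeric, min/max peak height of a meal
#'   excursion (mg/dL).
#' @param ar_coefficient level-persistence coefficient of the stochastic
#'   glucose excursion process; must lie in [0, 1) for stationarity.
#' @param trend_persistence velocity-persistence coefficient in [0, 1): the
#'   rate of change of the excursion process is itself AR(1) with this
#'   coefficient, reproducing the smooth, trending character of real CGM
#'   traces (glucose trend arrows persist over tens of minutes). 0 gives
#'   plain AR(1) jitter.
#' @param noise_sd stationary standard deviation of the excursion process
#'   (mg/dL).
#' @param missing_rate target fraction of unobserved samples when missingness
#'   is applied (in [0, 1)).
#' @param mean_gap_length mean length (in samples) of a contiguous sensor gap.
#' @param duration_days length of the recording in days (>= 1).
#' @param seed integer seed; all randomness in [generate_cgm_series()] flows
#'   from it.
#' @return A list of class `cgm_profile_params`.
#' @export
cgm_profile_params <- function(baseline_mean = 150,
                               baseline_sd = 20,
                               circadian_amplitude = 25,
                               meal_rate = 3,
                               meal_amplitude_range = c(60, 150),
                               ar_coefficient = 0.98,
                               trend_persistence = 0.85,
                               noise_sd = 35,
                               missing_rate = 0.1,
                               mean_gap_length = 6,
                               duration_days = 56,
                               seed = 1L) {
  stopifnot(length(meal_amplitude_range) == 2L)
  if (duration_days < 1) stop("duration_days must be >= 1", call. = FALSE)
  if (noise_sd < 0 || baseline_sd < 0) stop("standard deviations must be non-negative", call. = FALSE)
  if (baseline_mean < 40 || baseline_mean > 400) {
    stop("baseline_mean must lie in [40, 400] mg/dL", call. = FALSE)
  }
  if (ar_coefficient < 0 || ar_coefficient >= 1) {
    stop("ar_coefficient must lie in [0, 1) for stationarity", call. = FALSE)
  }
  if (trend_persistence < 0 || trend_persistence >= 1) {
    stop("trend_persistence must lie in [0, 1)", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (meal_rate < 0) stop("meal_rate must be non-negative", call. = FALSE)
  structure(
    list(
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      circadian_amplitude = circadian_amplitude, meal_rate = meal_rate,
      meal_amplitude_range = sort(meal_amplitude_range),
      ar_coefficient = ar_coefficient, trend_persistence = trend_persistence,
      noise_sd = noise_sd,
      missing_rate = missing_rate, mean_gap_length = mean_gap_length,
      duration_days = duration_days, seed = as.integer(seed)
    ),
    class = "cgm_profile_params"
  )
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

#' Simulate an Ohio-like CGM series
#'
#' Generates a fully observed 5-minute glucose series as the sum of a
#' slow-drifting baseline, a sinusoidal circadian term, randomly timed
#' gamma-shaped meal excursions and a trending stochastic excursion
#' process, clipped to the 40--400 mg/dL
#' sensor range. The same parameter object (including its seed) always yields
#' the identical series. Values are rounded to 0.01 mg/dL so that CSV
#' round-trips are exact.
#'
#' @param params a [cgm_profile_params()] object.
#' @param start POSIXct start time of the recording (default 2024-01-01 UTC).
#' @return A fully observed [cgm_series()] of `duration_days * 288` samples.
#' @export
generate_cgm_series <- function(params, start = as.POSIXct("2024-01-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(params, "cgm_profile_params"))
  n <- as.integer(round(params$duration_days * SAMPLES_PER_DAY))
  if (n < 1L) stop("duration_days must be >= 1", call. = FALSE)
  with_seed(params$seed, {
    hours <- (seq_len(n) - 1L) / 12 # 12 samples per hour

    # basal drift: daily random offsets, linearly interpolated
    n_knots <- params$duration_days + 1L
    knots <- stats::rnorm(n_knots, 0, params$baseline_sd)
    drift <- stats::approx(
      x = (seq_len(n_knots) - 1L) * 24, y = knots, xout = hours, rule = 2
    )$y
    baseline <- params$baseline_mean + drift

    circadian <- params$circadian_amplitude * sin(2 * pi * (hours - 10) / 24)

    # meal excursions: Poisson count, uniform times, gamma-shaped pulses
    # peaking 45 min after onset and decaying over ~5 h
    meals <- numeric(n)
    n_meals <- stats::rpois(1L, params$meal_rate * params$duration_days)
    if (n_meals > 0) {
      onsets <- sort(stats::runif(n_meals, 0, n))
      amps <- stats::runif(
        n_meals, params$meal_amplitude_range[1], params$meal_amplitude_range[2]
      )
      t_peak <- 9 # samples to peak (45 min)
      shape <- 2
      span <- 60L # samples of pulse support (5 h)
      for (i in seq_len(n_meals)) {
        i0 <- as.integer(ceiling(onsets[i]))
        idx <- i0:min(n, i0 + span)
        idx <- idx[idx >= 1L]
        if (!length(idx)) next
        dt <- idx - onsets[i]
        meals[idx] <- meals[idx] +
          amps[i] * (dt / t_peak)^shape * exp(shape * (1 - dt / t_peak))
      }
    }

    # stochastic excursion process: level persistence phi cascaded with
    # velocity persistence rho (d_t = phi d_{t-1} + v_t; v_t = rho v_{t-1}
    # + eta), i.e. AR(2) with roots phi and rho -- smooth, trending
    # wandering like real CGM. Innovation sd is chosen so the stationary sd
    # equals noise_sd.
    noise <- numeric(n)
    if (params$noise_sd > 0 && n > 1L) {
      phi <- params$ar_coefficient
      rho <- params$trend_persistence
      j <- 0:5000
      psi <- if (abs(phi - rho) < 1e-12) {
        (j + 1) * phi^j
      } else {
        (phi^(j + 1) - rho^(j + 1)) / (phi - rho)
      }
      innov_sd <- params$noise_sd / sqrt(sum(psi^2))
      eta <- stats::rnorm(n, 0, innov_sd)
      v <- stats::filter(eta, rho, method = "recursive")
      noise <- as.numeric(stats::filter(v, phi, method = "recursive"))
    }

    glucose <- round(pmin(400, pmax(40, baseline + circadian + meals + noise)), 2)
    cgm_series(time = start + 300 * (seq_len(n) - 1L), glucose = glucose)
  })
}

#' Mask contiguous sensor gaps in a CGM series
#'
#' Marks randomly placed contiguous gaps (geometric gap lengths with the given
#' mean) until the unobserved fraction is within 2 percentage points of
#' `missing_rate`. The first and last samples are never masked, so the
#' interpolation/extrapolation anchors always exist. Masked samples lose their
#' glucose value and are flagged unobserved.
#'
#' @param series a [cgm_series()].
#' @param missing_rate target unobserved fraction, in [0, 1).
#' @param mean_gap_length mean gap length in samples (>= 1).
#' @param seed integer seed for gap placement.
#' @return A [cgm_series()] with the same grid and masked samples.
#' @export
apply_missingness <- function(series, missing_rate, mean_gap_length = 6, seed = 1L) {
  stopifnot(inherits(series, "cgm_series"))
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (mean_gap_length < 1) stop("mean_gap_length must be >= 1", call. = FALSE)
  n <- nrow(series)
  if (missing_rate == 0 || n <= 2L) return(series)

  with_seed(seed, {
    masked <- !series$observed
    # allow at most 2pp overshoot; stop once within reach of the target
    budget <- floor((missing_rate + 0.02) * n) - sum(masked)
    target_n <- ceiling(missing_rate * n) - sum(masked)
    p_geom <- 1 / mean_gap_length
    guard <- 0L
    while (sum(masked & c(FALSE, rep(TRUE, n - 2L), FALSE)) < target_n && guard < 10000L) {
      guard <- guard + 1L
      len <- 1L + stats::rgeom(1L, p_geom)
      start <- sample.int(n - 2L, 1L) + 1L # interior position
      idx <- start:min(n - 1L, start + len - 1L)
      idx <- idx[!masked[idx]]
      new_total <- sum(masked) + length(idx)
      if (new_total > floor((missing_rate + 0.02) * n)) {
        keep <- floor((missing_rate + 0.02) * n) - sum(masked)
        if (keep <= 0L) break
        idx <- idx[seq_len(keep)]
      }
      masked[idx] <- TRUE
    }
    glucose <- series$glucose
    glucose[masked] <- NA_real_
    cgm_series(series$time, glucose, observed = !masked)
  })
}

#' Split a CGM series into training and testing periods
#'
#' Follows the standard Ohio T1D protocol: the final `test_days` days form the
#' testing set and everything before them the training set, so an eight-week
#' recording with `test_days = 10` splits into 46 training days (13,248
#' samples) and 10 testing days (2,880 samples).
#'
#' @param series a [cgm_series()].
#' @param test_days number of days at the end of the series to hold out.
#' @return A list with elements `train` and `test`, both [cgm_series()];
#'   concatenating them restores the input.
#' @export
split_train_test <- function(series, test_days = 10) {
  stopifnot(inherits(series, "cgm_series"))
  n <- nrow(series)
  n_test <- as.integer(round(test_days * SAMPLES_PER_DAY))
  if (n_test < 0L) stop("test_days must be non-negative", call. = FALSE)
  if (n_test >= n) {
    stop("test_days must leave at least one training sample", call. = FALSE)
  }
  split_at <- n - n_test
  train <- series[seq_len(split_at), , drop = FALSE]
  class(train) <- class(series)
  if (n_test > 0L) {
    test <- series[(split_at + 1L):n, , drop = FALSE]
  } else {
    test <- series[0L, , drop = FALSE]
  }
  class(test) <- class(series)
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test)
}
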