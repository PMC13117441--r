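#' Experiment configuration
#'
#' Describes a full comparison experiment: one or more subjects (synthetic
#' profiles or CGM CSV files), a set of prediction horizons, the shared
#' window/training settings, and the number of repeats per configuration.
#'
#' @param subjects named list; each element is either a
#'   [cgm_profile_params()] (a synthetic subject) or a file path to a CGM CSV.
#' @param horizons_min prediction horizons in minutes, each a multiple of 5
#'   (default `c(30, 60)`).
#' @param history_len history window length in samples (default 12 = 60 min).
#' @param epochs,batch_size,learning_rate training hyperparameters shared by
#'   all frameworks.
#' @param frameworks which frameworks to train (default all four).
#' @param repeats number of repeated runs per configuration (default 10).
#' @param test_days days held out at the end of each series for testing.
#' @param master_seed integer seed; per-run seeds are derived from it so that
#'   all frameworks see identical data shuffles within a repeat.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(subjects,
                              horizons_min = c(30, 60),
                              history_len = 12L,
                              epochs = 600L, batch_size = 128L,
                              learning_rate = 0.002,
                              frameworks = c("IL", "AL", "CL", "ACL"),
                              repeats = 10L,
                              test_days = 10,
                              master_seed = 1L) {
  if (is.null(names(subjects)) || any(names(subjects) == "")) {
    stop("subjects must be a named list", call. = FALSE)
  }
  ph_steps(horizons_min) # validates divisibility
  if (repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  frameworks <- match.arg(frameworks, c("IL", "AL", "CL", "ACL"), several.ok = TRUE)
  structure(
    list(
      subjects = subjects, horizons_min = horizons_min,
      history_len = as.integer(history_len),
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate, frameworks = frameworks,
      repeats = as.integer(repeats), test_days = test_days,
      master_seed = as.integer(master_seed)
    ),
    class = "experiment_config"
  )
}

# One reproducible seed per (subject, horizon, repeat); deliberately not a
# function of the framework, so competing frameworks share initial weights
# and shuffles within a repeat.
run_seed <- function(master, subject_i, horizon_i, rep_i) {
  as.integer((as.numeric(master) %% 100003 +
    7919 * subject_i + 104729 * horizon_i + 1299709 * rep_i) %% 2147483647)
}

load_subject_series <- function(spec) {
  if (inherits(spec, "cgm_profile_params")) {
    s <- generate_cgm_series(spec)
    if (spec$missing_rate > 0) {
      s <- apply_missingness(s, spec$missing_rate, spec$mean_gap_length,
        seed = spec$seed + 1L
      )
    }
    s
  } else if (is.character(spec)) {
    read_series_csv(spec)
  } else {
    stop("subject must be cgm_profile_params or a CSV path", call. = FALSE)
  }
}

#' Run the full framework-comparison experiment
#'
#' For every (subject, horizon): impute the training side by interpolation
#' and the held-out side by causal extrapolation, reframe into
#' history/horizon/post-horizon windows, fit the min-max scaler on training
#' windows only, then train every requested framework for `repeats` repeats
#' and evaluate each trained system's horizon-endpoint predictions on the
#' untouched test windows in mg/dL. Training and test windows come from
#' disjoint halves of the split; the test series is never seen during
#' training.
#'
#' @param cfg an [experiment_config()].
#' @param verbose print per-scenario progress to stderr.
#' @return List of class `experiment_results` with `per_run` (one row per
#'   subject x horizon x framework x repeat with the seven metrics) and
#'   `summary` (mean and sample SD over repeats via [aggregate_repeats()]).
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  rows <- list()
  for (si in seq_along(cfg$subjects)) {
    sid <- names(cfg$subjects)[si]
    series <- load_subject_series(cfg$subjects[[si]])
    parts <- split_train_test(series, cfg$test_days)
    train_series <- impute_training_series(parts$train)
    # anchor the first test gap on the last training samples so causal
    # extrapolation is defined even when the held-out period starts unobserved
    n_tr <- nrow(train_series)
    anchored <- cgm_series(
      c(train_series$time[(n_tr - 1L):n_tr], parts$test$time),
      c(train_series$glucose[(n_tr - 1L):n_tr], parts$test$glucose),
      c(TRUE, TRUE, parts$test$observed)
    )
    test_series <- impute_testing_series(anchored)[-(1:2), , drop = FALSE]
    class(test_series) <- class(parts$test)
    for (hi in seq_along(cfg$horizons_min)) {
      ph <- cfg$horizons_min[hi]
      m <- ph_steps(ph)
      wc_train <- window_config(cfg$history_len, m, include_post = TRUE)
      wc_test <- window_config(cfg$history_len, m, include_post = FALSE)
      train_ds <- reframe(train_series, wc_train)
      test_ds <- reframe(test_series, wc_test)
      scaler <- fit_scaler(train_ds)
      train_sc <- apply_scaler(train_ds, scaler)
      test_hist_sc <- apply_scaler(test_ds$histories, scaler)
      scenario <- sprintf("%s PH%d", sid, ph)
      for (fw in cfg$frameworks) {
        for (rep_i in seq_len(cfg$repeats)) {
          seed <- run_seed(cfg$master_seed, si, hi, rep_i)
          tc <- training_config(fw,
            epochs = cfg$epochs, batch_size = cfg$batch_size,
            learning_rate = cfg$learning_rate, seed = seed
          )
          sys <- train_system(train_sc, tc)
          pred <- apply_scaler(predict(sys, test_hist_sc), scaler, inverse = TRUE)
          met <- evaluate_forecasts(test_ds$ph_targets, pred)
          if (verbose) {
            message(sprintf(
              "%s %s rep %d: RMSE %.2f mg/dL", scenario, fw, rep_i, met$rmse
            ))
          }
          rows[[length(rows) + 1L]] <- data.frame(
            scenario = scenario, subject = sid, ph_min = ph,
            system = fw, repeat_i = rep_i, seed = seed,
            rmse = met$rmse, mae = met$mae, mape = met$mape, r2 = met$r2,
            mcc = met$mcc, se_lt_05 = met$se_lt_05, ase = met$ase
          )
        }
      }
    }
  }
  per_run <- do.call(rbind, rows)
  structure(
    list(per_run = per_run, summary = aggregate_repeats(per_run), config = cfg),
    class = "experiment_results"
  )
}

#' Aggregate repeated runs into mean and SD per scenario metric
#'
#' @param per_run data frame with columns `scenario`, `system` and metric
#'   columns, one row per run.
#' @return Data frame with one row per (scenario, system) holding
#'   `<metric>` (mean) and `<metric>_sd` (sample SD, n-1 denominator; 0 with
#'   a warning when only one run is available).
#' @export
aggregate_repeats <- function(per_run) {
  if (!nrow(per_run)) stop("no runs to aggregate", call. = FALSE)
  metrics <- intersect(names(metric_orientations()), names(per_run))
  key <- interaction(per_run$scenario, per_run$system, drop = TRUE)
  warned <- FALSE
  out <- lapply(split(per_run, key), function(g) {
    res <- g[1L, c("scenario", "system"), drop = FALSE]
    for (m in metrics) {
      res[[m]] <- mean(g[[m]])
      if (nrow(g) == 1L) {
        if (!warned) {
          warning("single run: reporting SD = 0", call. = FALSE)
          warned <<- TRUE
        }
        res[[paste0(m, "_sd")]] <- 0
      } else {
        res[[paste0(m, "_sd")]] <- stats::sd(g[[m]])
      }
    }
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$scenario, out$system), , drop = FALSE]
}

#' @export
print.experiment_results <- function(x, ...) {
  cat(sprintf(
    "<experiment_results> %d runs over %d scenario(s) x %d framework(s)\n",
    nrow(x$per_run), length(unique(x$per_run$scenario)),
    length(unique(x$per_run$system))
  ))
  invisible(x)
}
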