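test_that("regression metrics match hand arithmetic", {
  perfect <- regression_metrics(c(100, 200), c(100, 200))
  expect_equal(perfect, list(rmse = 0, mae = 0, mape = 0, r2 = 100))
  m <- regression_metrics(c(100, 200), c(110, 190))
  expect_equal(m$mae, 10)
  expect_equal(m$rmse, 10)
  expect_equal(m$mape, 7.5) # mean(10/100, 10/200) * 100
  # predicting the reference mean zeroes the coefficient of determination
  ref <- c(80, 120, 160, 200)
  expect_equal(regression_metrics(ref, rep(mean(ref), 4))$r2, 0)
  expect_error(regression_metrics(1:3, 1:2), "equal length")
})

test_that("metrics agree with loop-based recomputation on random inputs", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    ref <- runif(n, 40, 400)
    pred <- ref + rnorm(n, 0, 20)
    m <- regression_metrics(ref, pred)
    # naive loops
    se <- 0
    ae <- 0
    ape <- 0
    for (j in seq_len(n)) {
      se <- se + (ref[j] - pred[j])^2
      ae <- ae + abs(ref[j] - pred[j])
      ape <- ape + abs(ref[j] - pred[j]) / ref[j]
    }
    ss_tot <- 0
    for (j in seq_len(n)) ss_tot <- ss_tot + (ref[j] - mean(ref))^2
    expect_equal(m$rmse, sqrt(se / n), tolerance = 1e-9)
    expect_equal(m$mae, ae / n, tolerance = 1e-9)
    expect_equal(m$mape, 100 * ape / n, tolerance = 1e-9)
    expect_equal(m$r2, 100 * (1 - se / ss_tot), tolerance = 1e-9)
    expect_gte(m$rmse, m$mae)
  }
})

test_that("event classification uses strict 70/180 thresholds", {
  expect_identical(classify_event(65), "adverse")
  expect_identical(classify_event(150), "euglycaemic")
  expect_identical(classify_event(181), "adverse")
  expect_identical(classify_event(c(70, 180)), c("euglycaemic", "euglycaemic"))
  expect_error(classify_event(0), "positive")
})

test_that("MCC matches its closed form and symmetry", {
  expect_equal(mcc(5, 5, 0, 0), 1)
  expect_equal(mcc(3, 3, 3, 3), 0)
  expect_equal(mcc(6, 9, 1, 2), (54 - 2) / sqrt(7 * 8 * 10 * 11))
  expect_equal(mcc(6, 9, 1, 2), 0.6625, tolerance = 1e-4)
  # symmetric under swapping (TP<->TN, FP<->FN)
  expect_equal(mcc(6, 9, 1, 2), mcc(9, 6, 2, 1))
  und <- mcc(5, 0, 0, 3)
  expect_true(is.na(und))
  expect_match(attr(und, "reason"), "undefined")
  set.seed(7)
  for (i in 1:20) {
    cnt <- sample(1:30, 4, replace = TRUE)
    v <- mcc(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_gte(v, -1)
    expect_lte(v, 1)
  }
})

test_that("surveillance error is zero on the diagonal and monotone off it", {
  xs <- seq(40, 400, by = 5)
  expect_equal(as.numeric(surveillance_error(xs, xs)), rep(0, length(xs)))
  # monotone in |pred - ref| at fixed ref
  for (ref in c(60, 120, 250)) {
    up <- surveillance_error(rep(ref, 20), ref + seq(0, 95, by = 5))
    expect_true(all(diff(up) >= 0))
    down <- surveillance_error(rep(ref, 5), ref - seq(0, 20, by = 5))
    expect_true(all(diff(down) >= 0))
  }
  # bounded by the extreme-risk band ceiling
  expect_lte(max(surveillance_error(40, 400), surveillance_error(400, 40)), 4.5)
  expect_gt(surveillance_error(400, 40), 3.5) # extreme mismatch is extreme risk
  expect_warning(surveillance_error(30, 100), "clamped")
})

test_that("surveillance-error banding matches the published break points", {
  expect_identical(
    as.character(se_band(c(0.3, 0.7, 2.0, 3.0, 4.0))),
    c("none", "slight", "moderate", "high", "extreme")
  )
})

test_that("a supplied grid surface is interpolated bilinearly", {
  grid <- list(
    ref = c(40, 400), pred = c(40, 400),
    risk = matrix(c(0, 4, 4, 0), 2) # risk = scaled |pred - ref| corner surface
  )
  se <- surveillance_error(c(40, 400, 220), c(400, 40, 220), grid = grid)
  expect_equal(unname(se[1:2]), c(4, 4))
  expect_equal(unname(se[3]), 2) # centre of the bilinear patch
  expect_identical(attr(se, "surface"), "grid-bilinear")
})

test_that("clinical summary aggregates risk and event detection", {
  ref <- c(60, 100, 200, 250)
  cs <- clinical_summary(ref, ref)
  expect_equal(cs$ase, 0)
  expect_equal(cs$pct_no_risk, 100)
  expect_equal(as.numeric(cs$mcc), 1)
  expect_identical(sum(cs$band_histogram), length(ref))
  # one of two predictions inside the no-risk band
  cs2 <- clinical_summary(c(100, 100), c(102, 300))
  expect_equal(cs2$pct_no_risk, 50)
  expect_identical(sum(cs2$band_histogram), 2L)
  expect_error(clinical_summary(numeric(0), numeric(0)), "empty")
})

test_that("forecast evaluation scores the horizon endpoint by default", {
  ref <- matrix(c(100, 110, 120, 200, 210, 220), 2, byrow = TRUE)
  pred <- ref
  pred[, 3] <- pred[, 3] + c(10, -10)
  ev <- evaluate_forecasts(ref, pred)
  expect_equal(ev$rmse, 10) # endpoint errors only
  expect_equal(ev$mae, 10)
  all_steps <- evaluate_forecasts(ref, pred, timepoint = "all")
  expect_lt(all_steps$rmse, ev$rmse)
  expect_named(
    ev, c("rmse", "mae", "mape", "r2", "mcc", "se_lt_05", "ase")
  )
})
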