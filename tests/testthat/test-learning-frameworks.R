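test_that("predictive loss is the mean squared horizon error", {
  a <- matrix(c(0.5, 0.5), 1)
  b <- matrix(c(0.4, 0.8), 1)
  expect_equal(predictive_loss(a, a), 0)
  expect_equal(predictive_loss(a, b), 0.05) # mean of (0.01, 0.09)
  off <- matrix(0.2, 3, 4)
  expect_equal(predictive_loss(off + 0.3, off), 0.09)
  expect_error(predictive_loss(matrix(1, 2, 2), matrix(1, 2, 3)), "dimensions")
})

test_that("discriminator loss follows the real->0 / fake->1 convention", {
  eps <- 1e-9
  expect_lt(discriminator_loss(eps, 1 - eps), 1e-8) # perfect discriminator
  expect_equal(discriminator_loss(0.5, 0.5), 2 * log(2))
  expect_gt(discriminator_loss(1 - 1e-6, 1e-6), 20) # worst case
  expect_error(discriminator_loss(0, 0.5), "strictly inside")
  expect_error(discriminator_loss(0.5, 1), "strictly inside")
})

test_that("generator adversarial loss rewards fooling the discriminator", {
  eps <- 1e-9
  expect_lt(generator_adversarial_loss(eps), 1e-9) # fully fooled
  expect_equal(generator_adversarial_loss(0.5), 0.25)
  expect_gt(
    generator_adversarial_loss(1 - 1e-6),
    generator_adversarial_loss(0.5)
  )
  # strictly increasing in the fake score
  p <- seq(0.05, 0.95, by = 0.1)
  vals <- vapply(p, generator_adversarial_loss, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(generator_adversarial_loss(1), "strictly inside")
})

test_that("collaborative loss matches the shared error functional", {
  x <- matrix(runif(12), 3)
  expect_equal(collaborative_loss(x, x), 0)
  expect_equal(collaborative_loss(x + 0.1, x), 0.01)
})

test_that("collaborative gradient reaches the primary regressor weights", {
  n <- 6L
  m <- 3L
  pr <- build_primary_regressor(n, m, seed = 1)
  ar <- build_auxiliary_regressor(n, m, seed = 2)
  set.seed(3)
  H <- matrix(runif(2 * n), 2)
  PPH <- matrix(runif(2 * m), 2)
  lc_of <- function(pr) {
    ph_hat <- predict(pr, H)
    collaborative_loss(predict(ar, cbind(H, ph_hat)), PPH)
  }
  base <- lc_of(pr)
  # finite-difference derivative w.r.t. a primary weight is nonzero
  eps <- 1e-6
  grads <- vapply(1:10, function(i) {
    pr2 <- pr
    pr2$net$W[[1]][i] <- pr2$net$W[[1]][i] + eps
    (lc_of(pr2) - base) / eps
  }, numeric(1))
  expect_gt(max(abs(grads)), 1e-6)
  # freezing the primary output (constant horizon) removes the dependence
  frozen <- collaborative_loss(predict(ar, cbind(H, predict(pr, H) * 0 + 0.5)), PPH)
  pr2 <- pr
  pr2$net$W[[1]][1] <- pr2$net$W[[1]][1] + 1
  frozen2 <- collaborative_loss(predict(ar, cbind(H, predict(pr2, H) * 0 + 0.5)), PPH)
  expect_equal(frozen, frozen2)
})

test_that("zero-epoch training returns the freshly initialised regressor", {
  d <- small_training_data()$train
  cfg <- training_config("IL", epochs = 0, seed = 31)
  sys <- train_system(d, cfg)
  fresh <- build_primary_regressor(12, 6, seed = cgmforecast:::derive_seed(31, 1))
  expect_identical(predict(sys, d$histories), predict(fresh, d$histories))
})

test_that("system loss decomposes exactly into its active components", {
  d <- small_training_data()$train
  for (fw in c("IL", "AL", "CL", "ACL")) {
    h <- loss_history(train_system(d, training_config(fw, epochs = 2, seed = 8)))
    expect_equal(h$ls, h$lp + h$la + h$lc, tolerance = 1e-12)
    if (fw == "IL") expect_true(all(h$la == 0 & h$lc == 0))
    if (fw == "AL") expect_true(all(h$lc == 0) && any(h$la > 0))
    if (fw == "CL") expect_true(all(h$la == 0) && any(h$lc > 0))
    if (fw == "ACL") expect_true(any(h$la > 0) && any(h$lc > 0))
  }
})

test_that("training is bitwise reproducible under a seed", {
  d <- small_training_data()$train
  cfg <- training_config("ACL", epochs = 2, seed = 77)
  s1 <- train_system(d, cfg)
  s2 <- train_system(d, cfg)
  expect_identical(loss_history(s1), loss_history(s2))
  expect_identical(s1$primary$net$W, s2$primary$net$W)
})

test_that("detaching the auxiliary components reduces every framework to IL", {
  d <- small_training_data()$train
  il <- train_system(d, training_config("IL", epochs = 2, seed = 19))
  for (fw in c("AL", "CL", "ACL")) {
    red <- train_system(d, training_config(fw, epochs = 2, seed = 19),
      detach_auxiliary = TRUE
    )
    expect_identical(red$primary$net$W, il$primary$net$W)
    expect_equal(loss_history(red)$lp, loss_history(il)$lp, tolerance = 1e-12)
  }
})

test_that("blocking the collaborative gradient changes the one-step update", {
  d <- small_training_data()$train
  for (fw in c("CL", "ACL")) {
    cfg <- training_config(fw, epochs = 1, seed = 23)
    coupled <- train_system(d, cfg)
    blocked <- train_system(d, cfg, block_collab_gradient = TRUE)
    expect_false(identical(coupled$primary$net$W, blocked$primary$net$W))
  }
})

test_that("post-horizon targets are required for the interdependent frameworks", {
  d <- small_training_data()$train
  d$post_targets <- NULL
  for (fw in c("AL", "CL", "ACL")) {
    expect_error(
      train_system(d, training_config(fw, epochs = 1, seed = 1)),
      "post-horizon"
    )
  }
  expect_s3_class(
    train_system(d, training_config("IL", epochs = 1, seed = 1)),
    "trained_system"
  )
})

test_that("a trained regressor beats the naive baseline on a noiseless cycle", {
  # deterministic sinusoid: fully learnable, persistence clearly suboptimal
  s <- make_series(round(220 + 150 * sin(2 * pi * seq_len(600) / 96), 2))
  ds <- reframe(s, window_config(12, 6, include_post = TRUE))
  scl <- fit_scaler(ds)
  sys <- train_system(apply_scaler(ds, scl), training_config("IL", epochs = 200, seed = 3))
  pred <- apply_scaler(predict(sys, apply_scaler(ds$histories, scl)), scl, inverse = TRUE)
  rmse_model <- sqrt(mean((pred[, 6] - ds$ph_targets[, 6])^2))
  rmse_naive <- sqrt(mean((naive_forecast(ds$histories, 6)[, 6] - ds$ph_targets[, 6])^2))
  expect_lt(rmse_model, rmse_naive)
})

test_that("prediction uses only the primary regressor and is batch-invariant", {
  d <- small_training_data()$train
  sys <- train_system(d, training_config("ACL", epochs = 1, seed = 3))
  H <- d$histories[1:5, ]
  all_at_once <- predict(sys, H)
  one_by_one <- t(vapply(1:5, function(i) predict(sys, H[i, ])[1, ], numeric(6)))
  expect_equal(all_at_once, one_by_one, tolerance = 1e-12)
  expect_identical(all_at_once, predict(sys$primary, H))
  expect_true(all(predict(sys, matrix(0, 1, 12)) >= 0))
  expect_error(predict(sys, matrix(0, 1, 11)), "input width")
})

test_that("the naive forecast repeats the last observation", {
  expect_equal(naive_forecast(c(130, 125, 120), 6), rep(120, 6))
  expect_equal(naive_forecast(rep(100, 12), 3), rep(100, 3))
  # strictly rising series: endpoint absolute error is slope * m
  h <- seq(100, 155, by = 5)
  target <- 155 + 5 * (1:6)
  expect_equal(abs(naive_forecast(h, 6) - target)[6], 5 * 6)
  expect_error(naive_forecast(numeric(0), 3), "non-empty")
})
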