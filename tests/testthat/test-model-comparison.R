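test_that("block ranking respects orientation and averages ties", {
  expect_equal(rank_block(c(19.36, 18.87, 19.05, 18.77), "lower"), c(4, 2, 3, 1))
  expect_equal(rank_block(c(81.81, 80.42, 81.75, 82.37), "higher"), c(2, 4, 3, 1))
  expect_equal(rank_block(c(12.50, 12.50, 12.66, 12.25), "lower"), c(2.5, 2.5, 4, 1))
  expect_error(rank_block(c(1, NA), "lower"), "finite")
  expect_error(rank_block(5, "lower"), "at least 2")
})

test_that("the rank matrix has one block per scenario-metric pair", {
  res <- ohio_benchmark_results()
  res$scenario <- paste(res$dataset, res$scenario)
  rm <- build_rank_matrix(res)
  expect_identical(nrow(rm), 24L * 7L) # 168 blocks
  expect_identical(ncol(rm), 4L)
  expect_true(all(abs(rowSums(rm) - 10) < 1e-12)) # 4*5/2 per block
  one <- build_rank_matrix(res[res$scenario == res$scenario[1], ])
  expect_identical(nrow(one), 7L)
  incomplete <- res[-2, ]
  expect_error(build_rank_matrix(incomplete), "incomplete")
})

test_that("mean ranks conserve the rank total", {
  res <- ohio_benchmark_results()
  res$scenario <- paste(res$dataset, res$scenario)
  mr <- average_ranks(build_rank_matrix(res))
  expect_equal(sum(mr), 10)
  # unanimous ordering gives integer mean ranks
  toy <- data.frame(
    scenario = rep(c("a", "b"), each = 4),
    system = rep(c("A", "B", "C", "D"), 2),
    rmse = c(1, 2, 3, 4, 10, 20, 30, 40)
  )
  expect_equal(unname(average_ranks(build_rank_matrix(toy))), c(1, 2, 3, 4))
})

test_that("Friedman statistic matches the closed form in degenerate cases", {
  # identical systems in every block: statistic 0, p = 1
  flat <- matrix(rep(c(2.5, 2.5, 2.5, 2.5), 10), 10, byrow = TRUE)
  class(flat) <- c("rank_matrix", "matrix")
  fr <- friedman_test(flat)
  expect_equal(fr$statistic, 0)
  expect_equal(fr$p_value, 1)
  expect_false(fr$reject)
  # identical untied ordering in 10 blocks of 4: 12n/(k(k+1)) * sum - 3n(k+1) = 30
  strict <- matrix(rep(1:4, 10), 10, byrow = TRUE)
  class(strict) <- c("rank_matrix", "matrix")
  expect_equal(friedman_test(strict)$statistic, 30)
  expect_error(friedman_test(flat[, 1, drop = FALSE]), "at least 2")
})

test_that("Friedman output matches stats::friedman.test on random tables", {
  set.seed(2024)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    k <- sample(3:6, 1)
    vals <- matrix(rnorm(n * k), n, k)
    if (i %% 3 == 0) vals <- round(vals) # force ties
    colnames(vals) <- paste0("s", 1:k)
    res <- data.frame(
      scenario = rep(seq_len(n), each = k),
      system = rep(colnames(vals), n),
      rmse = as.vector(t(vals))
    )
    rm <- build_rank_matrix(res, metrics = "rmse")
    mine <- friedman_test(rm)
    ref <- stats::friedman.test(vals)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("Friedman is invariant under monotone within-block transforms", {
  set.seed(5)
  vals <- matrix(rnorm(40), 10, 4)
  res <- data.frame(
    scenario = rep(1:10, each = 4),
    system = rep(letters[1:4], 10),
    rmse = as.vector(t(vals))
  )
  res2 <- res
  res2$rmse <- exp(res2$rmse) * 3 + 1 # strictly monotone
  f1 <- friedman_test(build_rank_matrix(res, metrics = "rmse"))
  f2 <- friedman_test(build_rank_matrix(res2, metrics = "rmse"))
  expect_equal(f1$statistic, f2$statistic)
})

test_that("Nemenyi critical difference and p-values match a direct recomputation", {
  res <- ohio_benchmark_results()
  res$scenario <- paste(res$dataset, res$scenario)
  rm <- build_rank_matrix(res)
  nem <- nemenyi_posthoc(rm, alpha = 0.05)
  k <- 4
  n <- nrow(rm)
  expect_equal(
    nem$critical_difference,
    qtukey(0.95, 4, Inf) / sqrt(2) * sqrt(k * (k + 1) / (6 * n)),
    tolerance = 1e-12
  )
  expect_equal(nem$critical_difference, 0.362, tolerance = 5e-3)
  # independent recomputation of each pairwise p from scratch
  mr <- colMeans(unclass(rm))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      z <- abs(mr[[i]] - mr[[j]]) / sqrt(k * (k + 1) / (6 * n))
      p_ref <- ptukey(z * sqrt(2), k, Inf, lower.tail = FALSE)
      expect_equal(nem$p_matrix[i, j], p_ref, tolerance = 1e-9)
    }
  }
  expect_equal(nem$p_matrix, t(nem$p_matrix))
  expect_equal(unname(diag(nem$p_matrix)), rep(1, 4))
  # Holm decisions agree with p.adjust on the off-diagonal p-values
  pv <- nem$p_matrix[upper.tri(nem$p_matrix)]
  expect_equal(
    nem$holm_p[upper.tri(nem$holm_p)],
    p.adjust(pv, "holm"),
    tolerance = 1e-12
  )
})

test_that("Nemenyi matches brute-force recomputation on random tables", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:15, 1)
    k <- sample(3:5, 1)
    vals <- matrix(rnorm(n * k), n, k)
    colnames(vals) <- paste0("s", 1:k)
    res <- data.frame(
      scenario = rep(seq_len(n), each = k),
      system = rep(colnames(vals), n),
      rmse = as.vector(t(vals))
    )
    rm <- build_rank_matrix(res, metrics = "rmse")
    nem <- suppressWarnings(nemenyi_posthoc(rm))
    # brute force: rank each row by sorting, mean over rows
    brute_ranks <- t(apply(vals, 1, function(r) order(order(r))))
    brute_mr <- colMeans(brute_ranks)
    expect_equal(unname(nem$mean_ranks), unname(brute_mr), tolerance = 1e-9)
    se <- sqrt(k * (k + 1) / (6 * n))
    for (a in 1:(k - 1)) {
      for (b in (a + 1):k) {
        p_ref <- ptukey(abs(brute_mr[[a]] - brute_mr[[b]]) / se * sqrt(2), k, Inf,
          lower.tail = FALSE
        )
        expect_equal(nem$p_matrix[a, b], p_ref, tolerance = 1e-9)
      }
    }
  }
})

test_that("identical mean ranks are never declared significantly different", {
  rm <- matrix(rep(c(1, 1.5, 3.5, 4), 8), 8, byrow = TRUE)
  # swap the first two systems in alternate blocks so their mean ranks tie
  rm[c(1, 3, 5, 7), 1] <- 1.5
  rm[c(1, 3, 5, 7), 2] <- 1
  class(rm) <- c("rank_matrix", "matrix")
  colnames(rm) <- letters[1:4]
  nem <- suppressWarnings(nemenyi_posthoc(rm))
  expect_equal(nem$mean_ranks[["a"]], nem$mean_ranks[["b"]])
  expect_false(nem$cd_significant[1, 2])
  expect_equal(nem$p_matrix[1, 2], 1)
})

test_that("critical-difference diagram orders systems and joins close groups", {
  mr <- c(A = 1.2, B = 1.4, C = 3.0, D = 3.1)
  dg <- cd_diagram_data(mr, cd = 0.5)
  expect_identical(dg$positions$system, c("A", "B", "C", "D"))
  expect_identical(nrow(dg$connectors), 2L) # {A,B} and {C,D}
  expect_false(any(dg$connectors$from == "B" & dg$connectors$to == "C"))
  # far-apart pair: no connector
  none <- cd_diagram_data(c(A = 1, B = 3), cd = 0.5)
  expect_identical(nrow(none$connectors), 0L)
  # everything within cd: single spanning connector
  all_close <- cd_diagram_data(c(A = 1, B = 1.1, C = 1.2), cd = 0.5)
  expect_identical(nrow(all_close$connectors), 1L)
  expect_identical(all_close$connectors$from, "A")
  expect_identical(all_close$connectors$to, "C")
})
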