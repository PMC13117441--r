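#' Metric orientations
#'
#' Which direction is better for each of the seven scenario metrics.
#'
#' @return Named character vector: `"lower"` or `"higher"` per metric.
#' @export
metric_orientations <- function() {
  c(
    rmse = "lower", mae = "lower", mape = "lower", ase = "lower",
    r2 = "higher", mcc = "higher", se_lt_05 = "higher"
  )
}

#' Rank competing systems within one block
#'
#' Rank 1 is best under the given orientation; ties receive the mean of the
#' tied rank positions (average ranks).
#'
#' @param values numeric vector, one value per system (k >= 2, finite).
#' @param orientation `"lower"` (smaller is better) or `"higher"`.
#' @return Numeric vector of ranks summing to `k(k+1)/2`.
#' @export
rank_block <- function(values, orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  if (length(values) < 2L) stop("need at least 2 systems", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  if (orientation == "higher") values <- -values
  rank(values, ties.method = "average")
}

#' Build the (scenario x metric) rank matrix
#'
#' One block per combination of scenario and metric; within each block the
#' competing systems are ranked by [rank_block()] under each metric's
#' orientation.
#'
#' @param results data frame with columns `scenario`, `system` and one column
#'   per metric (mean values over repeats); every (scenario, system) pair
#'   must be present exactly once.
#' @param metrics which metric columns to use (default: the seven standard
#'   metrics present in `results`).
#' @return A `rank_matrix`: numeric matrix (blocks x systems) with block
#'   labels as row names, plus attributes `k` and `n_blocks`.
#' @export
build_rank_matrix <- function(results, metrics = NULL) {
  orient <- metric_orientations()
  if (is.null(metrics)) metrics <- intersect(names(orient), names(results))
  if (!length(metrics)) stop("no metric columns found", call. = FALSE)
  unknown <- setdiff(metrics, names(orient))
  if (length(unknown)) {
    stop(sprintf("no orientation defined for metric(s): %s",
      paste(unknown, collapse = ", ")), call. = FALSE)
  }
  scenarios <- unique(results$scenario)
  systems <- unique(results$system)
  k <- length(systems)
  out <- matrix(NA_real_, nrow = length(scenarios) * length(metrics), ncol = k,
    dimnames = list(NULL, systems)
  )
  labels <- character(nrow(out))
  row <- 0L
  for (sc in scenarios) {
    sub <- results[results$scenario == sc, , drop = FALSE]
    pos <- match(systems, sub$system)
    if (anyNA(pos) || nrow(sub) != k) {
      stop(sprintf("incomplete results for scenario '%s'", sc), call. = FALSE)
    }
    for (met in metrics) {
      row <- row + 1L
      vals <- sub[[met]][pos]
      if (anyNA(vals)) {
        stop(sprintf("missing value for scenario '%s', metric '%s'", sc, met),
          call. = FALSE
        )
      }
      out[row, ] <- rank_block(vals, orient[[met]])
      labels[row] <- paste(sc, met, sep = " | ")
    }
  }
  rownames(out) <- labels
  structure(out, k = k, n_blocks = nrow(out), class = c("rank_matrix", "matrix"))
}

#' Mean rank of each system over all blocks
#'
#' @param rm a `rank_matrix`.
#' @return Named numeric vector of mean ranks; sums to `k(k+1)/2`.
#' @export
average_ranks <- function(rm) {
  if (!nrow(rm)) stop("empty rank matrix", call. = FALSE)
  colMeans(unclass(rm))
}

#' Friedman test on a rank matrix
#'
#' Chi-square approximation of the Friedman statistic with the standard tie
#' correction, testing the null that all systems perform identically across
#' the matched blocks.
#'
#' @param rm a `rank_matrix` (blocks x systems, average ranks within blocks).
#' @param alpha significance level (default 0.05).
#' @return List with `statistic`, `df`, `p_value`, `reject`, `mean_ranks`.
#' @export
friedman_test <- function(rm, alpha = 0.05) {
  k <- ncol(rm)
  n <- nrow(rm)
  if (k < 2L) stop("need at least 2 systems", call. = FALSE)
  if (n < 2L) stop("need at least 2 blocks", call. = FALSE)
  r <- unclass(rm)
  # tie correction: sum over blocks of (t^3 - t) per tied group
  ties <- sum(apply(r, 1L, function(row) {
    tg <- table(row)
    sum(tg^3 - tg)
  }))
  num <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) - ties / (k - 1)
  stat <- if (den <= 0) 0 else num / den
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  list(
    statistic = stat, df = k - 1L, p_value = p, reject = p < alpha,
    alpha = alpha, mean_ranks = colMeans(r),
    method = "Friedman chi-square approximation with tie correction"
  )
}

#' Nemenyi post hoc comparison with Holm-adjusted decisions
#'
#' Pairwise comparisons of mean ranks via the studentised-range distribution.
#' Two systems differ significantly under the critical-difference rule iff
#' their mean-rank gap is at least `CD = q(alpha, k) * sqrt(k(k+1)/(6n))`
#' (with `q` the studentised range quantile divided by sqrt(2)). The pairwise
#' Nemenyi p-values are additionally Holm-Bonferroni adjusted and both
#' decision sets are reported.
#'
#' @param rm a `rank_matrix`.
#' @param alpha significance level.
#' @return List with `p_matrix` (symmetric, unit diagonal),
#'   `critical_difference`, `mean_ranks`, `cd_significant` and
#'   `holm_significant` (logical matrices), `holm_p` and the global
#'   `friedman` result.
#' @export
nemenyi_posthoc <- function(rm, alpha = 0.05) {
  k <- ncol(rm)
  n <- nrow(rm)
  fr <- friedman_test(rm, alpha)
  if (!fr$reject) {
    warning("Friedman test did not reject; post hoc comparisons are exploratory")
  }
  mean_ranks <- colMeans(unclass(rm))
  se <- sqrt(k * (k + 1) / (6 * n))
  q_alpha <- stats::qtukey(1 - alpha, k, Inf) / sqrt(2)
  cd <- q_alpha * se
  p <- diag(1, k)
  dimnames(p) <- list(colnames(rm), colnames(rm))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      q_obs <- abs(mean_ranks[i] - mean_ranks[j]) / se * sqrt(2)
      p[i, j] <- p[j, i] <- stats::ptukey(q_obs, k, Inf, lower.tail = FALSE)
    }
  }
  gap <- abs(outer(mean_ranks, mean_ranks, `-`))
  upper <- upper.tri(p)
  holm <- p
  holm[upper] <- stats::p.adjust(p[upper], method = "holm")
  holm[lower.tri(holm)] <- t(holm)[lower.tri(holm)]
  list(
    p_matrix = p,
    critical_difference = cd,
    mean_ranks = mean_ranks,
    cd_significant = gap >= cd & !diag(k),
    holm_p = holm,
    holm_significant = holm < alpha & !diag(k),
    alpha = alpha,
    friedman = fr
  )
}

#' Data for a critical-difference diagram
#'
#' Axis positions and connector segments for the standard CD diagram: systems
#' are placed at their mean ranks (best first) and maximal groups whose
#' internal mean-rank gaps are all below the critical difference are joined
#' by a connector.
#'
#' @param mean_ranks named numeric vector of mean ranks.
#' @param cd critical difference.
#' @return List with `positions` (data frame: system, mean_rank, order) and
#'   `connectors` (data frame: from, to, lo, hi), plus `cd`.
#' @export
cd_diagram_data <- function(mean_ranks, cd) {
  ord <- order(mean_ranks)
  pos <- data.frame(
    system = names(mean_ranks)[ord],
    mean_rank = unname(mean_ranks[ord]),
    order = seq_along(ord)
  )
  # maximal runs of systems whose extreme gap is < cd
  segs <- list()
  k <- nrow(pos)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && pos$mean_rank[j + 1L] - pos$mean_rank[i] < cd) j <- j + 1L
    if (j > i) segs[[length(segs) + 1L]] <- c(i, j)
  }
  if (length(segs)) {
    segs <- segs[!vapply(seq_along(segs), function(s) {
      any(vapply(segs[-s], function(o) o[1] <= segs[[s]][1] && o[2] >= segs[[s]][2] &&
        !identical(o, segs[[s]]), logical(1)))
    }, logical(1))]
    connectors <- do.call(rbind, lapply(segs, function(s) {
      data.frame(
        from = pos$system[s[1]], to = pos$system[s[2]],
        lo = pos$mean_rank[s[1]], hi = pos$mean_rank[s[2]]
      )
    }))
    connectors <- unique(connectors)
  } else {
    connectors <- data.frame(
      from = character(), to = character(),
      lo = numeric(), hi = numeric()
    )
  }
  list(positions = pos, connectors = connectors, cd = cd)
}

#' Plot a critical-difference diagram
#'
#' Base-graphics rendering of [cd_diagram_data()]: a rank axis with one tick
#' per system and horizontal bars joining groups that are not significantly
#' different.
#'
#' @param diagram result of [cd_diagram_data()].
#' @param main plot title.
#' @return Invisibly, `diagram`.
#' @export
plot_cd_diagram <- function(diagram, main = "Critical-difference diagram") {
  pos <- diagram$positions
  k <- nrow(pos)
  rng <- range(pos$mean_rank)
  pad <- max(0.25, 0.1 * diff(rng))
  graphics::plot(NULL,
    xlim = c(rng[1] - pad, rng[2] + pad), ylim = c(0, k + 2),
    axes = FALSE, xlab = "mean rank", ylab = "", main = main
  )
  graphics::axis(1)
  graphics::points(pos$mean_rank, rep(k + 1, k), pch = 19)
  graphics::text(pos$mean_rank, rep(k + 1, k), pos$system, pos = 3, cex = 0.9)
  if (nrow(diagram$connectors)) {
    for (i in seq_len(nrow(diagram$connectors))) {
      graphics::segments(
        diagram$connectors$lo[i], k + 0.5 - 0.35 * i,
        diagram$connectors$hi[i], k + 0.5 - 0.35 * i,
        lwd = 3
      )
    }
  }
  graphics::mtext(sprintf("CD = %.3f", diagram$cd), side = 3, line = 0, cex = 0.8)
  invisible(diagram)
}

#' Published framework benchmark results
#'
#' Loads the packaged summary of the published per-scenario evaluation of the
#' four learning frameworks on the two Ohio T1D benchmark cohorts: mean
#' values of the seven metrics for every combination of 12 subjects
#' (six per cohort), two prediction horizons (30/60 min) and four systems
#' (IL, AL, CL, ACL) -- 24 scenarios, 96 rows.
#'
#' @return Data frame with columns `dataset`, `scenario`, `system` and the
#'   seven metric columns.
#' @export
ohio_benchmark_results <- function() {
  path <- system.file("extdata", "ohio_framework_results.csv",
    package = "cgmforecast", mustWork = TRUE
  )
  utils::read.csv(path, stringsAsFactors = FALSE)
}
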