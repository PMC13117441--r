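#' Mathematical regression metrics
#'
#' Computes RMSE, MAE and MAPE of predicted against reference glucose, plus
#' the coefficient of determination r2, all on the mg/dL scale:
#' `RMSE = sqrt(mean((BG - BGhat)^2))`, `MAE = mean(|BG - BGhat|)`,
#' `MAPE = 100 * mean(|BG - BGhat| / BG)` and
#' `r2 = 1 - sum((BG - BGhat)^2) / sum((BG - mean(BG))^2)`. Both r2 and MAPE
#' are reported in percent (r2 multiplied by 100).
#'
#' @param reference numeric vector of observed glucose (mg/dL, all > 0).
#' @param predicted numeric vector of predicted glucose (mg/dL).
#' @return Named list with `rmse`, `mae`, `mape`, `r2`.
#' @export
regression_metrics <- function(reference, predicted) {
  if (length(reference) != length(predicted)) {
    stop("reference and predicted must have equal length", call. = FALSE)
  }
  if (length(reference) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(reference <= 0)) stop("reference glucose must be positive", call. = FALSE)
  err <- reference - predicted
  list(
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    mape = 100 * mean(abs(err) / reference),
    r2 = 100 * (1 - sum(err^2) / sum((reference - mean(reference))^2))
  )
}

#' Classify a glucose value as adverse or euglycaemic
#'
#' Adverse glycaemic events are hypoglycaemia (BG < 70 mg/dL) or
#' hyperglycaemia (BG > 180 mg/dL); values of exactly 70 or 180 mg/dL are
#' euglycaemic (the thresholds are strict).
#'
#' @param bg numeric vector of glucose values (mg/dL, > 0).
#' @return Character vector, `"adverse"` or `"euglycaemic"`.
#' @export
classify_event <- function(bg) {
  if (any(bg <= 0)) stop("glucose must be positive", call. = FALSE)
  ifelse(bg < 70 | bg > 180, "adverse", "euglycaemic")
}

#' Matthews correlation coefficient from confusion counts
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in [-1, 1].
#' When any factor of the denominator is zero the coefficient is undefined;
#' this is reported as `NA` with a `reason` attribute rather than coerced
#' to 0.
#'
#' @param tp,tn,fp,fn non-negative confusion counts (positive class =
#'   adverse event).
#' @return Scalar in [-1, 1], or `NA` with attribute `reason`.
#' @export
mcc <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  denom2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) {
    return(structure(NA_real_,
      reason = "undefined: a row or column of the confusion matrix is empty"
    ))
  }
  ((as.numeric(tp) * tn) - (as.numeric(fp) * fn)) / sqrt(denom2)
}

#' Surveillance error of a prediction
#'
#' Scores the clinical risk of predicting `predicted` when the reference
#' value is `reference`. Risk bands: [0, 0.5) none, [0.5, 1.5) slight,
#' [1.5, 2.5) moderate, [2.5, 3.5) high, >= 3.5 extreme.
#'
#' By default the risk surface is an analytic approximation of the
#' surveillance-error grid: `SE = s * |log(predicted) - log(reference)|` with
#' `s = 4.5 / log(400/40)`, which is zero on the diagonal, increases
#' monotonically with the relative error, reaches 4.5 at the most extreme
#' mismatch of the sensor range, and weights a given absolute error more
#' heavily at low (hypoglycaemic) glucose -- the qualitative structure of the
#' consensus grid. A digitised grid surface can be supplied instead via
#' `grid`, in which case the score is bilinear interpolation over it; which
#' surface was used is recorded in the result's `surface` attribute.
#'
#' Inputs outside [40, 400] mg/dL are clamped to the boundary with a warning.
#'
#' @param reference,predicted numeric vectors of glucose values (mg/dL).
#' @param grid optional list with `ref`, `pred` (ascending grid coordinates)
#'   and `risk` (matrix `length(ref)` x `length(pred)`).
#' @return Numeric vector of risk scores, attribute `surface` naming the
#'   surface used.
#' @export
surveillance_error <- function(reference, predicted, grid = NULL) {
  if (length(reference) != length(predicted)) {
    stop("reference and predicted must have equal length", call. = FALSE)
  }
  clamp <- function(x) {
    if (any(x < 40 | x > 400)) {
      warning("glucose outside [40, 400] mg/dL clamped to the grid boundary")
    }
    pmin(400, pmax(40, x))
  }
  r <- clamp(reference)
  p <- clamp(predicted)
  if (is.null(grid)) {
    se <- (4.5 / log(10)) * abs(log(p) - log(r))
    attr(se, "surface") <- "analytic-log"
  } else {
    se <- bilinear_lookup(grid, r, p)
    attr(se, "surface") <- "grid-bilinear"
  }
  se
}

bilinear_lookup <- function(grid, r, p) {
  stopifnot(all(c("ref", "pred", "risk") %in% names(grid)))
  fi <- function(coord, x) {
    i <- findInterval(x, coord, all.inside = TRUE)
    w <- (x - coord[i]) / (coord[i + 1L] - coord[i])
    list(i = i, w = pmin(1, pmax(0, w)))
  }
  a <- fi(grid$ref, r)
  b <- fi(grid$pred, p)
  z <- grid$risk
  (1 - a$w) * (1 - b$w) * z[cbind(a$i, b$i)] +
    (1 - a$w) * b$w * z[cbind(a$i, b$i + 1L)] +
    a$w * (1 - b$w) * z[cbind(a$i + 1L, b$i)] +
    a$w * b$w * z[cbind(a$i + 1L, b$i + 1L)]
}

#' Band label of a surveillance-error score
#'
#' @param se numeric vector of surveillance-error scores.
#' @return Factor with levels none/slight/moderate/high/extreme.
#' @export
se_band <- function(se) {
  cut(se,
    breaks = c(-Inf, 0.5, 1.5, 2.5, 3.5, Inf),
    labels = c("none", "slight", "moderate", "high", "extreme"),
    right = FALSE
  )
}

#' Clinical evaluation summary
#'
#' Computes the clinical metrics for a set of predictions: the average
#' surveillance error (ASE), the percentage of predictions carrying no
#' clinical risk (SE < 0.5), the per-band histogram, and the Matthews
#' correlation coefficient of adverse-event detection (predicted event class
#' against reference event class).
#'
#' @inheritParams surveillance_error
#' @return List of class `clinical_report` with `ase`, `pct_no_risk`,
#'   `band_histogram`, `mcc`, `counts` (TP/TN/FP/FN) and `surface`.
#' @export
clinical_summary <- function(reference, predicted, grid = NULL) {
  if (!length(reference)) stop("empty input", call. = FALSE)
  se <- surveillance_error(reference, predicted, grid = grid)
  bands <- table(se_band(se))
  ref_adv <- classify_event(reference) == "adverse"
  pred_adv <- classify_event(pmax(predicted, 1e-6)) == "adverse"
  counts <- c(
    tp = sum(ref_adv & pred_adv), tn = sum(!ref_adv & !pred_adv),
    fp = sum(!ref_adv & pred_adv), fn = sum(ref_adv & !pred_adv)
  )
  structure(
    list(
      ase = mean(se),
      pct_no_risk = 100 * mean(se < 0.5),
      band_histogram = bands,
      mcc = mcc(counts[["tp"]], counts[["tn"]], counts[["fp"]], counts[["fn"]]),
      counts = counts,
      surface = attr(se, "surface")
    ),
    class = "clinical_report"
  )
}

#' @export
print.clinical_report <- function(x, ...) {
  cat(sprintf(
    "<clinical_report> ASE %.3f | SE<0.5 %.1f%% | MCC %s (%s surface)\n",
    x$ase, x$pct_no_risk,
    if (is.na(x$mcc)) "undefined" else sprintf("%.3f", x$mcc), x$surface
  ))
  invisible(x)
}

#' Full mathematical + clinical evaluation of horizon forecasts
#'
#' Evaluates predicted against reference horizon matrices on the mg/dL scale.
#' By default only the horizon endpoint of each window is scored (the
#' standard glucose-forecasting convention); `timepoint = "all"` scores every
#' predicted step.
#'
#' @param reference N x m matrix of real horizon values (mg/dL).
#' @param predicted N x m matrix of predicted horizon values (mg/dL).
#' @param timepoint `"endpoint"` or `"all"`.
#' @param grid optional surveillance-error grid (see [surveillance_error()]).
#' @return Named list with the seven scenario metrics: `rmse`, `mae`, `mape`,
#'   `r2` (%), `mcc` (%), `se_lt_05` (%), `ase`.
#' @export
evaluate_forecasts <- function(reference, predicted,
                               timepoint = c("endpoint", "all"), grid = NULL) {
  timepoint <- match.arg(timepoint)
  reference <- as.matrix(reference)
  predicted <- as.matrix(predicted)
  if (!all(dim(reference) == dim(predicted))) {
    stop("reference and predicted must have identical dimensions", call. = FALSE)
  }
  if (timepoint == "endpoint") {
    ref <- reference[, ncol(reference)]
    pred <- predicted[, ncol(predicted)]
  } else {
    ref <- as.vector(reference)
    pred <- as.vector(predicted)
  }
  math <- regression_metrics(ref, pred)
  clin <- clinical_summary(ref, pred, grid = grid)
  list(
    rmse = math$rmse, mae = math$mae, mape = math$mape, r2 = math$r2,
    mcc = 100 * as.numeric(clin$mcc),
    se_lt_05 = clin$pct_no_risk, ase = clin$ase
  )
}
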