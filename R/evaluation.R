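#' @include training.R
NULL

#' Regression metrics
#'
#' Pearson correlation coefficient, mean absolute error and root mean square
#' error between predicted and true affinities (pK units). When either
#' vector is constant the PCC is undefined and returned as `NA` with
#' `pcc_defined = FALSE` rather than silently propagating `NaN`.
#'
#' @param predicted,true equal-length numeric vectors, length >= 2.
#' @return A list of class `pla_metrics`: `pcc`, `mae`, `rmse`, `n`,
#'   `pcc_defined`.
#' @export
compute_metrics <- function(predicted, true) {
  if (length(predicted) != length(true))
    stop("predicted and true must have equal length")
  if (length(predicted) < 2L) stop("metrics require at least 2 samples")
  if (!all(is.finite(predicted)) || !all(is.finite(true)))
    stop("metrics require finite values")
  d <- predicted - true
  defined <- stats::sd(predicted) > 0 && stats::sd(true) > 0
  structure(list(pcc = if (defined) stats::cor(predicted, true) else NA_real_,
                 mae = mean(abs(d)), rmse = sqrt(mean(d^2)),
                 n = length(d), pcc_defined = defined),
            class = "pla_metrics")
}

#' @export
print.pla_metrics <- function(x, ...) {
  cat(sprintf("PCC %s  MAE %.3f  RMSE %.3f  (n = %d)\n",
              if (x$pcc_defined) sprintf("%.3f", x$pcc) else "undefined",
              x$mae, x$rmse, x$n))
  invisible(x)
}

#' Threshold screening evaluation
#'
#' Thresholds both the true and predicted affinities at an activity cutoff
#' (higher pK = more active; a sample is an inhibitor iff its value is at or
#' above the threshold) and tabulates the confusion matrix. With
#' `mode = "rank"` the predicted side is instead called positive for the
#' top-k ranked predictions, where k is the number of true inhibitors.
#'
#' @param predicted,true equal-length numeric pK vectors.
#' @param threshold activity cutoff in pK units.
#' @param mode `"value"` (threshold the predicted pK) or `"rank"`.
#' @return A list of class `pla_confusion`: `tp`, `fp`, `tn`, `fn`,
#'   `accuracy` (percent), `threshold`, `n`.
#' @export
screening_eval <- function(predicted, true, threshold, mode = c("value", "rank")) {
  mode <- match.arg(mode)
  if (length(predicted) != length(true))
    stop("predicted and true must have equal length")
  if (length(predicted) < 1L) stop("screening requires at least 1 sample")
  truth <- true >= threshold
  call_ <- if (mode == "value") predicted >= threshold
           else rank(-predicted, ties.method = "first") <= sum(truth)
  tp <- sum(call_ & truth); fp <- sum(call_ & !truth)
  tn <- sum(!call_ & !truth); fn <- sum(!call_ & truth)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = 100 * (tp + tn) / length(true),
                 threshold = threshold, n = length(true)),
            class = "pla_confusion")
}

#' @export
print.pla_confusion <- function(x, ...) {
  cat(sprintf("threshold %.2f pK: TP %d FP %d TN %d FN %d  accuracy %.2f%%\n",
              x$threshold, x$tp, x$fp, x$tn, x$fn, x$accuracy))
  invisible(x)
}

#' Screening evaluation over several thresholds
#'
#' @inheritParams screening_eval
#' @param thresholds numeric vector of activity cutoffs (>= 1).
#' @return A list of `pla_confusion`, one per threshold, in input order.
#' @export
threshold_sweep <- function(predicted, true, thresholds, mode = c("value", "rank")) {
  mode <- match.arg(mode)
  if (length(thresholds) < 1L) stop("need at least one threshold")
  lapply(thresholds, function(t) screening_eval(predicted, true, t, mode))
}

#' Project features to 2D by principal components
#'
#' Mean-centered projection of a feature matrix onto its top two principal
#' axes, as used to visualize the fused global features. The sign of each
#' axis is fixed so its largest-magnitude loading is positive, making plots
#' reproducible across platforms.
#'
#' @param features numeric matrix (n >= 3 rows, d >= 2 columns).
#' @return A list: `coords` (n x 2), `explained` (variance fractions of the
#'   two axes, nonincreasing).
#' @export
project_features_2d <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 3L || ncol(features) < 2L)
    stop("need at least 3 samples and 2 feature dimensions")
  centered <- scale(features, center = TRUE, scale = FALSE)
  if (max(abs(centered)) == 0) stop("rank-0 feature matrix: all rows identical")
  pc <- stats::prcomp(centered, center = FALSE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) rot[, j] <- -rot[, j]
  }
  coords <- centered %*% rot
  if (k < 2L) coords <- cbind(coords, 0)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = coords, explained = c(expl[1], if (k > 1L) expl[2] else 0))
}
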