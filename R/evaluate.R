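#' ROC curve and trapezoidal AUC
#'
#' Candidate thresholds are the midpoints between consecutive distinct scores,
#' plus sentinels below and above all scores, so every achievable confusion
#' table appears once. A patient is called rare when `score > threshold`
#' (strict). The AUC is the trapezoidal area over these points, which equals
#' the rank/concordance statistic `P(score_rare > score_abundant) +
#' 0.5 P(equal)` for any tie pattern.
#'
#' @param scores Numeric scores, higher = more rare-like.
#' @param labels Binary labels (1 = rare class); both classes required.
#' @return An object of class `roc_curve`: list with `points` (data.frame
#'   `threshold, sensitivity, specificity`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (anyNA(scores) || anyNA(labels)) stop("missing scores or labels")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  sens <- vapply(thr, function(t) mean(pos > t), 0)
  spec <- vapply(thr, function(t) mean(neg <= t), 0)
  fpr <- 1 - spec
  auc <- sum(diff(rev(fpr)) * (rev(sens)[-1] + rev(sens)[-length(sens)]) / 2)
  structure(list(points = data.frame(threshold = thr, sensitivity = sens,
                                     specificity = spec),
                 auc = auc,
                 score_range = range(scores)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d operating points, AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Youden-index optimal threshold
#'
#' Returns the threshold maximizing J = sensitivity + specificity - 1. Ties
#' resolve to the lowest threshold, favoring sensitivity. A degenerate curve
#' (constant scores, max J = 0) is returned with a warning.
#'
#' @param roc A `roc_curve` from [roc_auc()].
#' @return The optimal threshold (a midpoint between observed scores).
#' @export
youden_threshold <- function(roc) {
  p <- roc$points
  if (nrow(p) == 0) stop("empty ROC curve")
  j <- p$sensitivity + p$specificity - 1
  jmax <- max(j)
  if (jmax <= 1e-12) {
    warning("degenerate ROC curve: Youden index is 0 at every threshold")
  }
  cand <- p$threshold[j >= jmax - 1e-12]
  best <- min(cand)
  # sentinel winners (degenerate all-rare / no-rare operating points) are
  # mapped to finite thresholds with the identical confusion table
  if (best == -Inf) best <- roc$score_range[1] - 1
  if (best == Inf) best <- roc$score_range[2] + 1
  best
}

#' Confusion-matrix performance metrics
#'
#' A patient is called rare when `score > threshold` (strict inequality; ties
#' at the threshold go to the abundant class). Reports the confusion counts,
#' accuracy, sensitivity, specificity, their geometric mean
#' `G-mean = sqrt(sensitivity * specificity)` and the AUC.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = rare).
#' @param threshold Finite decision threshold.
#' @return A `metrics_report`: list with `threshold`, `tp`, `tn`, `fp`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`, `gmean`, `auc`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(list(threshold = threshold, tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 sensitivity = sens, specificity = spec,
                 gmean = sqrt(sens * spec),
                 auc = roc_auc(scores, labels)$auc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("metrics_report (threshold %.4f):\n",
                     "  TP %d  TN %d  FP %d  FN %d\n",
                     "  accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%",
                     "  G-mean %.1f%%  AUC %.1f%%\n"),
              x$threshold, x$tp, x$tn, x$fp, x$fn, 100 * x$accuracy,
              100 * x$sensitivity, 100 * x$specificity, 100 * x$gmean,
              100 * x$auc))
  invisible(x)
}

#' Evaluate an ensemble run at the Youden-optimal threshold
#'
#' Builds the ROC curve of the final soft-vote scores, picks the
#' Youden-optimal threshold on those same leave-one-out scores (as-published
#' convention; see the vignette for the optimism caveat) and reports the
#' confusion metrics.
#'
#' @param run A `loo_run` from [loo_predict()], or a data.frame with columns
#'   `final_score` and `true_label`.
#' @return A `metrics_report` (with the `roc_curve` attached as attribute
#'   `roc`).
#' @export
evaluate_run <- function(run) {
  pred <- if (inherits(run, "loo_run")) run$predictions else run
  roc <- roc_auc(pred$final_score, pred$true_label)
  thr <- youden_threshold(roc)
  rep <- confusion_metrics(pred$final_score, pred$true_label, thr)
  attr(rep, "roc") <- roc
  rep
}

#' Single-model leave-one-out baseline
#'
#' The "original model" baseline shares the ensemble's backbone (Gini
#' selection then calibrated linear SVM) but trains one model per fold on all
#' remaining patients — no under-sampling, no voting. On imbalanced data this
#' baseline is expected to underperform the resampled ensemble.
#'
#' @param cohort A complete `cohort_table`.
#' @param config A [run_config()]; only `seed`, `n_trees`, `svm_cost`,
#'   `svm_tol` and `standardize_mode` are used.
#' @return A `metrics_report` with the per-patient scores attached as
#'   attribute `predictions`.
#' @export
original_model_baseline <- function(cohort, config = run_config()) {
  if (!inherits(cohort, "cohort_table")) stop("not a cohort_table")
  X_raw <- cohort_matrix(cohort)
  if (anyNA(X_raw)) stop("cohort contains missing values; impute first")
  y <- cohort$data$outcome
  cont <- cohort$schema$name[cohort$schema$kind == "continuous"]
  X <- switch(config$standardize_mode,
    "as-published" = std_matrix(X_raw, cont, seq_len(nrow(X_raw))),
    "train-only"   = X_raw,
    "none"         = X_raw)
  n <- nrow(X)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- if (config$standardize_mode == "train-only") {
      std_matrix(X_raw, cont, setdiff(seq_len(n), i))
    } else X
    rows <- setdiff(seq_len(n), i)
    fit <- fit_base_model(Xi[rows, , drop = FALSE], y[rows],
                          n_trees = config$n_trees, cost = config$svm_cost,
                          tol = config$svm_tol,
                          seed = derive_seed(config$seed, i, 0, 0))
    scores[i] <- predict_score(fit, Xi[i, ])
  }
  roc <- roc_auc(scores, y)
  rep <- confusion_metrics(scores, y, youden_threshold(roc))
  attr(rep, "predictions") <- data.frame(
    patient_id = cohort$data$patient_id, true_label = y, final_score = scores)
  rep
}
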