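#' Exact Shapley explanation of a linear base model
#'
#' For a linear model under feature independence the Shapley value of feature
#' i has the closed form `w_i * (x_i - mean(background_i))` in margin space;
#' features outside the selected mask have weight 0 and therefore contribution
#' exactly 0. Margin-space contributions are mapped into score space by the
#' secant slope of the calibration curve between the background-mean margin
#' and the evaluation margin, so the additivity identity
#' `base_value + sum(contributions) = score` holds exactly for the reported
#' [0,1] score. The base value is the calibrated score at the background-mean
#' margin (the model's expected prediction when no feature value is known);
#' positive contributions push toward the rare class.
#'
#' @param fit A `base_model_fit`.
#' @param x Feature vector for the explained patient (model scale).
#' @param background Training feature matrix (the fit's training set).
#' @param patient_id Optional identifier carried on the result.
#' @param level Label for the explanation level (`"ratio1"`, ...,
#'   `"ensemble"`).
#' @return An `explanation`: list with `patient_id`, `level`, `base_value`,
#'   `contributions` (score space, named), `margin_contributions`,
#'   `base_margin` and `score`.
#' @export
linear_shap <- function(fit, x, background, patient_id = NA_character_,
                        level = "model") {
  f <- names(fit$weights)
  if (is.null(colnames(background)) || !all(f %in% colnames(background))) {
    stop("background matrix must cover the fit's features")
  }
  xv <- if (is.null(names(x))) {
    if (length(x) != length(f)) stop("feature vector length mismatch")
    stats::setNames(x, f)
  } else {
    if (!all(f %in% names(x))) stop("feature vector does not cover the fit's features")
    x[f]
  }
  mu <- colMeans(background[, f, drop = FALSE])
  phi_m <- fit$weights * (xv - mu)
  margin <- sum(fit$weights * xv) + fit$intercept
  base_margin <- sum(fit$weights * mu) + fit$intercept
  a <- fit$calibration["slope"]; b <- fit$calibration["offset"]
  score <- unname(stats::plogis(a * margin + b))
  base_value <- unname(stats::plogis(a * base_margin + b))
  k <- if (abs(margin - base_margin) < 1e-12) 0 else {
    (score - base_value) / (margin - base_margin)
  }
  new_explanation(patient_id, level, base_value, phi_m * k, phi_m,
                  base_margin, score)
}

new_explanation <- function(patient_id, level, base_value, contributions,
                            margin_contributions, base_margin, score) {
  structure(list(patient_id = patient_id, level = level,
                 base_value = base_value, contributions = contributions,
                 margin_contributions = margin_contributions,
                 base_margin = base_margin, score = score),
            class = "explanation")
}

#' Explain one ratio's vote
#'
#' Explains the sub-model whose score was propagated by the majority vote
#' (the max-scoring rare voter or min-scoring abundant voter), so the
#' explained score equals the ratio's aggregated score exactly.
#'
#' @param vote A `ratio_vote` from [majority_vote()].
#' @param fit The `base_model_fit` of the vote-selected sub-model.
#' @param x Feature vector of the explained patient.
#' @param background The selected sub-model's training matrix.
#' @param patient_id Optional identifier.
#' @return An `explanation` at level `ratio<r>`.
#' @export
explain_ratio <- function(vote, fit, x, background,
                          patient_id = NA_character_) {
  ex <- linear_shap(fit, x, background, patient_id = patient_id,
                    level = paste0("ratio", vote$ratio))
  stopifnot(abs(ex$score - vote$score) < 1e-9)
  ex
}

#' Ensemble-level explanation
#'
#' Averages the per-ratio explanations feature-wise: the ensemble contribution
#' of a feature is the mean of its per-ratio contributions (aligned on the
#' union of feature sets, absent features counting 0), the ensemble base value
#' is the mean of the ratio base values, and the explained score is the mean
#' of the ratio scores — consistent with [soft_vote()], so additivity is
#' preserved by linearity. A feature pushing in opposite directions across
#' ratios therefore nets out toward zero.
#'
#' @param explanations List of per-ratio `explanation` objects for the same
#'   patient.
#' @return An `explanation` at level `"ensemble"`.
#' @export
explain_ensemble <- function(explanations) {
  if (length(explanations) == 0) stop("no explanations to average")
  feats <- unique(unlist(lapply(explanations, function(e) names(e$contributions))))
  align <- function(v) {
    out <- stats::setNames(numeric(length(feats)), feats)
    out[names(v)] <- v
    out
  }
  contrib <- Reduce(`+`, lapply(explanations, function(e) align(e$contributions)))
  contrib_m <- Reduce(`+`, lapply(explanations, function(e) align(e$margin_contributions)))
  k <- length(explanations)
  new_explanation(
    patient_id = explanations[[1]]$patient_id,
    level = "ensemble",
    base_value = mean(vapply(explanations, `[[`, 0, "base_value")),
    contributions = contrib / k,
    margin_contributions = contrib_m / k,
    base_margin = mean(vapply(explanations, `[[`, 0, "base_margin")),
    score = mean(vapply(explanations, `[[`, 0, "score")))
}

#' Per-patient additive explanation of an ensemble run
#'
#' Produces the per-ratio explanations of the vote-selected sub-models plus
#' the ensemble-averaged explanation for one patient of a completed
#' leave-one-out run (requires `keep_artifacts = TRUE` in the run config).
#' With `method = "mean-over-models"` every sub-model of each ratio is
#' explained and averaged instead of the vote-selected one (requires
#' `keep_all_fits = TRUE`); this alternative weighs all 100 sub-models equally
#' and does not correspond to the propagated vote score.
#'
#' @param run A `loo_run` with artifacts.
#' @param patient_id Patient identifier (or integer row index).
#' @param method `"vote-selected"` (default) or `"mean-over-models"`.
#' @return List with one `explanation` per ratio plus `$ensemble`, and
#'   `$table`: a data.frame `feature, contribution_ratio<r>...,
#'   contribution_ensemble`.
#' @export
explain_patient <- function(run, patient_id,
                            method = c("vote-selected", "mean-over-models")) {
  method <- match.arg(method)
  if (!inherits(run, "loo_run")) stop("not a loo_run")
  if (is.null(run$artifacts)) {
    stop("run has no artifacts; rerun loo_predict with keep_artifacts = TRUE")
  }
  i <- if (is.numeric(patient_id)) as.integer(patient_id) else {
    match(patient_id, run$predictions$patient_id)
  }
  if (is.na(i) || i < 1 || i > nrow(run$predictions)) {
    stop("unknown patient: ", patient_id)
  }
  pid <- run$predictions$patient_id[i]
  row <- run$folds[i]  # global row of the explained patient
  cont <- run$schema$name[run$schema$kind == "continuous"]
  X <- if (run$config$standardize_mode == "train-only") {
    std_matrix(run$X_raw, cont, setdiff(seq_len(nrow(run$X_raw)), row))
  } else {
    run$artifacts$X
  }
  out <- list()
  for (r in as.character(run$config$ratios)) {
    sel <- run$artifacts$sel[[i]][[r]]
    vote_score <- run$predictions[[paste0("score_ratio", r)]][i]
    if (method == "vote-selected") {
      ex <- linear_shap(sel$fit, X[row, ], X[sel$rows, , drop = FALSE],
                        patient_id = pid, level = paste0("ratio", r))
      stopifnot(abs(ex$score - vote_score) < 1e-9)
    } else {
      if (is.null(sel$all_fits)) {
        stop("mean-over-models needs keep_all_fits = TRUE in the run config")
      }
      plans <- run$artifacts$plans[[i]][[r]]
      exs <- lapply(seq_along(sel$all_fits), function(m) {
        linear_shap(sel$all_fits[[m]], X[row, ], X[plans[[m]], , drop = FALSE],
                    patient_id = pid, level = paste0("ratio", r))
      })
      ex <- explain_ensemble(exs)
      ex$level <- paste0("ratio", r)
    }
    out[[paste0("ratio", r)]] <- ex
  }
  out$ensemble <- explain_ensemble(out[as.character(paste0("ratio", run$config$ratios))])
  tab <- data.frame(feature = names(out$ensemble$contributions))
  for (r in as.character(run$config$ratios)) {
    tab[[paste0("contribution_ratio", r)]] <-
      unname(out[[paste0("ratio", r)]]$contributions[tab$feature])
  }
  tab$contribution_ensemble <- unname(out$ensemble$contributions[tab$feature])
  out$table <- tab
  out
}

#' @export
print.explanation <- function(x, top_k = 8, ...) {
  cat(sprintf("explanation [%s] patient %s: score %.3f = base %.3f + sum(contributions) %.3f\n",
              x$level, x$patient_id, x$score, x$base_value,
              sum(x$contributions)))
  ord <- order(abs(x$contributions), decreasing = TRUE)
  top <- utils::head(ord, top_k)
  for (j in top) {
    if (x$contributions[j] == 0) next
    cat(sprintf("  %-18s %+0.4f %s\n", names(x$contributions)[j],
                x$contributions[j],
                if (x$contributions[j] > 0) "(pushes toward rare class)"
                else "(pushes away)"))
  }
  invisible(x)
}
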