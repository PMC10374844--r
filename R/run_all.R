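#' Ensemble run configuration
#'
#' Defaults replicate the published configuration: 100 sub-models per ratio,
#' ratios 1:1/1:2/1:3, 100-tree forests for feature selection, linear SVM with
#' C = 1, and standardization of the continuous features on the entire dataset
#' before cross-validation ("as-published"). The leakage-safe alternative
#' (`standardize_mode = "train-only"`) refits the scaler per fold on the
#' training pool only; `"none"` skips scaling (for pre-scaled or synthetic
#' matrices).
#'
#' @param seed Master seed; all fold/ratio/model seeds derive from it.
#' @param n_models Sub-models per ratio.
#' @param ratios Integer vector of abundant-class multiples.
#' @param n_trees Trees in the selection forest.
#' @param svm_cost SVM regularization constant C.
#' @param svm_tol SVM solver tolerance.
#' @param standardize_mode One of `"as-published"`, `"train-only"`, `"none"`.
#' @param keep_artifacts Keep per-fold masks/plans/selected fits (needed by
#'   [explain_patient()] and the frequency summaries).
#' @param keep_all_fits Additionally keep all sub-model fits (needed only for
#'   the mean-over-models explanation variant; memory-heavy).
#' @param verbose Emit fold progress messages.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L, n_models = 100L, ratios = c(1L, 2L, 3L),
                       n_trees = 100L, svm_cost = 1, svm_tol = 1e-4,
                       standardize_mode = c("as-published", "train-only", "none"),
                       keep_artifacts = TRUE, keep_all_fits = FALSE,
                       verbose = FALSE) {
  standardize_mode <- match.arg(standardize_mode)
  if (n_models < 1) stop("n_models must be at least 1")
  if (any(ratios < 1) || any(ratios != round(ratios))) {
    stop("ratios must be positive integers")
  }
  structure(list(seed = as.integer(seed), n_models = as.integer(n_models),
                 ratios = as.integer(ratios), n_trees = as.integer(n_trees),
                 svm_cost = svm_cost, svm_tol = svm_tol,
                 standardize_mode = standardize_mode,
                 keep_artifacts = keep_artifacts,
                 keep_all_fits = keep_all_fits, verbose = verbose),
            class = "run_config")
}

#' Run the full pipeline and write an output bundle
#'
#' Orchestrates the whole analysis: simulate (unless a cohort is supplied),
#' impute, standardize, leave-one-out ensemble prediction, evaluation,
#' feature frequencies and per-patient explanations, writing every result as
#' a plain-text file into `out_dir`. Reruns with the same configuration and
#' seed reproduce the bundle exactly.
#'
#' Files written: `cohort.csv` (if simulated), `imputation_log.csv`,
#' `predictions.csv`, `metrics.json`, `roc.csv`, `frequencies.csv`,
#' `explanation_<patient>.csv` and `config.json`.
#'
#' @param config A [run_config()].
#' @param cohort A `cohort_table`, or `NULL` to simulate from `gen_config`.
#' @param gen_config A `generator_config` used when `cohort` is `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param explain_patients Character vector of patient ids to explain.
#' @return Invisibly, a list with `cohort`, `run`, `metrics`, `frequencies`
#'   and the output paths.
#' @export
run_all <- function(config = run_config(), cohort = NULL,
                    gen_config = default_config(seed = config$seed),
                    out_dir = ".", explain_patients = character()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (is.null(cohort)) {
    cohort <- generate_cohort(gen_config)
    paths$cohort <- file.path(out_dir, "cohort.csv")
    write_cohort(cohort, paths$cohort)
  }
  imp <- impute_missing(cohort)
  paths$imputation_log <- file.path(out_dir, "imputation_log.csv")
  utils::write.csv(imp$records, paths$imputation_log, row.names = FALSE)

  run <- loo_predict(imp$table, config)
  paths$predictions <- file.path(out_dir, "predictions.csv")
  pred_out <- run$predictions
  num <- vapply(pred_out, is.double, TRUE)
  pred_out[num] <- lapply(pred_out[num], function(v) round(v, 6))
  utils::write.csv(pred_out, paths$predictions, row.names = FALSE)

  metrics <- evaluate_run(run)
  roc <- attr(metrics, "roc")
  paths$metrics <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(
    list(threshold = round(metrics$threshold, 6),
         tp = metrics$tp, tn = metrics$tn, fp = metrics$fp, fn = metrics$fn,
         accuracy = round(metrics$accuracy, 6),
         sensitivity = round(metrics$sensitivity, 6),
         specificity = round(metrics$specificity, 6),
         gmean = round(metrics$gmean, 6),
         auc = round(metrics$auc, 6),
         n_vote_ties = run$n_vote_ties),
    paths$metrics, auto_unbox = TRUE, pretty = TRUE)
  paths$roc <- file.path(out_dir, "roc.csv")
  roc_out <- attr(metrics, "roc")$points
  roc_out[] <- lapply(roc_out, function(v) round(v, 6))
  utils::write.csv(roc_out, paths$roc, row.names = FALSE)

  freqs <- NULL
  if (config$keep_artifacts) {
    freqs <- merge(selection_frequency(run),
                   significance_frequency(run),
                   by = c("feature", "ratio", "n_sets"))
    freqs <- freqs[order(freqs$ratio, freqs$feature), ]
    freqs$selection_pct <- round(freqs$selection_pct, 2)
    freqs$significance_pct <- round(freqs$significance_pct, 2)
    paths$frequencies <- file.path(out_dir, "frequencies.csv")
    utils::write.csv(freqs, paths$frequencies, row.names = FALSE)
  }
  for (pid in explain_patients) {
    ex <- explain_patient(run, pid)
    p <- file.path(out_dir, paste0("explanation_", pid, ".csv"))
    tab <- ex$table
    num <- vapply(tab, is.double, TRUE)
    tab[num] <- lapply(tab[num], function(v) round(v, 6))
    utils::write.csv(tab, p, row.names = FALSE)
    paths[[paste0("explanation_", pid)]] <- p
  }
  paths$config <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(cohort = cohort, run = run, metrics = metrics,
                 frequencies = freqs, paths = paths))
}
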