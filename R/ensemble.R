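# Deterministic position-derived seed scheme: every sub-model's seed is a
# modular hash of (master seed, fold, ratio, model), so any single sub-model
# can be re-derived in isolation and folds can be computed in any order with
# bit-identical results.
derive_seed <- function(master, ...) {
  s <- as.double(master) %% 2147483647
  for (v in c(...)) {
    s <- (s * 69069 + as.double(v) + 1) %% 2147483647
  }
  as.integer(s) + 1L
}

#' Resampling plan for one ratio
#'
#' Builds `n_models` under-sampled training index sets at class ratio `1:r`:
#' every set contains all available rare-class indices and exactly
#' `ratio * N_rare` abundant-class indices drawn uniformly without replacement
#' within a set, independently across sets (sets may overlap).
#'
#' @param y Binary outcome vector of the training pool (the "other patients"
#'   of a leave-one-out fold), 1 = rare class.
#' @param ratio Integer abundant multiple r (1, 2 or 3 at published defaults).
#' @param n_models Number of sets (default 100).
#' @param seed Integer seed.
#' @return A `resampling_plan`: list with `ratio`, `n_models`, `rare` (index
#'   vector) and `abundant_sets` (list of index vectors into `y`).
#' @export
make_training_sets <- function(y, ratio, n_models = 100L, seed = 1L) {
  rare <- which(y == 1)
  abundant <- which(y == 0)
  n_ab <- ratio * length(rare)
  if (length(rare) == 0) stop("training pool has no rare-class samples")
  if (length(abundant) < n_ab) {
    stop(sprintf("abundant pool too small for ratio 1:%d (%d available, %d needed)",
                 ratio, length(abundant), n_ab))
  }
  if (length(abundant) == n_ab) {
    warning(sprintf("abundant pool exactly matches ratio 1:%d; all %d training sets are identical",
                    ratio, n_models))
  }
  set.seed(seed)
  sets <- lapply(seq_len(n_models), function(m) sort(sample(abundant, n_ab)))
  structure(list(ratio = as.integer(ratio), n_models = as.integer(n_models),
                 rare = rare, abundant_sets = sets),
            class = "resampling_plan")
}

#' Majority vote over one ratio's sub-models
#'
#' The winning class is the modal class over the sub-model votes (a 50/50 tie
#' resolves to the rare class, consistent with the model's screening purpose,
#' and is flagged). The aggregated score is the maximum score among sub-models
#' voting rare when the rare class wins, and the minimum score among
#' sub-models voting abundant when the abundant class wins.
#'
#' @param classes Integer vector of per-model class votes (1 = rare).
#' @param scores Numeric vector of per-model scores in [0,1].
#' @param ratio Ratio label carried on the result.
#' @return A `ratio_vote`: list with `ratio`, `class`, `score`, `model_index`
#'   (which sub-model supplied the aggregated score), `tie`, `classes`,
#'   `scores`.
#' @export
majority_vote <- function(classes, scores, ratio = NA_integer_) {
  if (length(classes) == 0) stop("empty vote list")
  if (length(classes) != length(scores)) stop("classes/scores length mismatch")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0,1]")
  n1 <- sum(classes == 1)
  n0 <- length(classes) - n1
  tie <- n1 == n0
  winner <- if (n1 >= n0) 1L else 0L
  idx <- which(classes == winner)
  model_index <- idx[if (winner == 1L) which.max(scores[idx]) else which.min(scores[idx])]
  structure(list(ratio = ratio, class = winner,
                 score = scores[model_index], model_index = model_index,
                 tie = tie, classes = classes, scores = scores),
            class = "ratio_vote")
}

#' Soft vote across ratios
#'
#' @param scores Numeric vector of per-ratio aggregated scores in [0,1].
#' @return Their arithmetic mean.
#' @export
soft_vote <- function(scores) {
  if (length(scores) == 0) stop("no scores to average")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0,1]")
  mean(scores)
}

# Standardize the continuous columns of a feature matrix using statistics
# (population sd) computed on `rows_fit`; used for the train-only mode.
std_matrix <- function(X, cont, rows_fit) {
  for (f in cont) {
    v <- X[rows_fit, f]
    mu <- mean(v)
    s <- sqrt(mean((v - mu)^2))
    if (s == 0) stop("feature '", f, "' has zero variance in the training pool")
    X[, f] <- (X[, f] - mu) / s
  }
  X
}

# All models of one leave-one-out fold: for each ratio, a resampling plan and
# n_models selection+SVM fits, then the per-ratio majority vote and the final
# soft vote.
fit_fold <- function(X, y, i, config) {
  others <- setdiff(seq_len(nrow(X)), i)
  y_oth <- y[others]
  votes <- list()
  masks <- list()
  plans <- list()
  sel <- list()
  for (r in config$ratios) {
    plan <- make_training_sets(y_oth, r, config$n_models,
                               seed = derive_seed(config$seed, i, r, 0))
    n_rare <- length(plan$rare)
    scores <- numeric(config$n_models)
    classes <- integer(config$n_models)
    mask_mat <- matrix(FALSE, config$n_models, ncol(X),
                       dimnames = list(NULL, colnames(X)))
    fits <- vector("list", config$n_models)  # transient; only the vote-selected fit is retained
    rows_list <- vector("list", config$n_models)
    for (m in seq_len(config$n_models)) {
      rows <- others[c(plan$rare, plan$abundant_sets[[m]])]
      stopifnot(!(i %in% rows),                       # leakage guard
                sum(y[rows] == 0) == r * n_rare,      # exact 1:r ratio
                sum(y[rows] == 1) == n_rare)
      fit <- fit_base_model(X[rows, , drop = FALSE], y[rows],
                            n_trees = config$n_trees, cost = config$svm_cost,
                            tol = config$svm_tol,
                            seed = derive_seed(config$seed, i, r, m))
      scores[m] <- predict_score(fit, X[i, ])
      classes[m] <- as.integer(scores[m] > 0.5)
      mask_mat[m, ] <- fit$selected
      rows_list[[m]] <- rows
      fits[[m]] <- fit
    }
    vote <- majority_vote(classes, scores, ratio = r)
    key <- as.character(r)
    votes[[key]] <- vote
    masks[[key]] <- mask_mat
    plans[[key]] <- rows_list
    sel[[key]] <- list(fit = fits[[vote$model_index]],
                       rows = rows_list[[vote$model_index]],
                       model_index = vote$model_index,
                       all_fits = if (config$keep_all_fits) fits)
  }
  final_score <- soft_vote(vapply(votes, function(v) v$score, 0))
  list(votes = votes, final_score = final_score, masks = masks,
       plans = plans, sel = sel)
}

#' Leave-one-out ensemble prediction
#'
#' Each patient in turn is held out; the remaining patients form the training
#' pool from which `n_models` under-sampled training sets per ratio are drawn.
#' Every sub-model runs the shared backbone (Gini feature selection, then a
#' calibrated linear SVM) and scores the held-out patient; per-ratio majority
#' voting and final soft voting produce the ensemble score. At published
#' defaults (100 models, ratios 1:1/1:2/1:3) each fold trains 300 sub-models.
#' The whole run is deterministic given `config$seed`; fold/ratio/model seeds
#' are position-derived (see the package vignette), so results do not depend
#' on execution order.
#'
#' @param cohort A complete (imputed) `cohort_table`.
#' @param config A [run_config()].
#' @param folds Optional integer vector of patient rows to hold out and score
#'   (default: every patient). Scoring a subset is useful for large simulation
#'   studies: each scored patient still gets a fully leakage-free prediction
#'   from models trained on all other patients, and fold seeds are
#'   position-derived, so the scores of a subset are bit-identical to the
#'   corresponding scores of a full run.
#' @return An object of class `loo_run`: list with `predictions` (data.frame:
#'   `patient_id`, `true_label`, per-ratio class and score columns,
#'   `final_score`), `n_vote_ties`, `config`, the matrices used, and — when
#'   `config$keep_artifacts` — `artifacts` with per-fold selection masks,
#'   training-set plans and the vote-selected fits (used by
#'   [explain_patient()], [selection_frequency()] and
#'   [significance_frequency()]).
#' @export
loo_predict <- function(cohort, config = run_config(), folds = NULL) {
  if (!inherits(cohort, "cohort_table")) stop("not a cohort_table")
  X_raw <- cohort_matrix(cohort)
  if (anyNA(X_raw)) {
    stop("cohort contains missing values; run impute_missing() first")
  }
  y <- cohort$data$outcome
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("both classes need at least 2 patients")
  }
  cont <- cohort$schema$name[cohort$schema$kind == "continuous"]
  X <- switch(config$standardize_mode,
    "as-published" = std_matrix(X_raw, cont, seq_len(nrow(X_raw))),
    "train-only"   = X_raw,  # standardized per fold below
    "none"         = X_raw)
  n <- nrow(X)
  if (is.null(folds)) folds <- seq_len(n)
  folds <- as.integer(folds)
  if (any(folds < 1 | folds > n) || anyDuplicated(folds)) {
    stop("folds must be distinct patient row indices")
  }
  fold_fits <- vector("list", length(folds))
  for (j in seq_along(folds)) {
    i <- folds[j]
    Xi <- if (config$standardize_mode == "train-only") {
      std_matrix(X_raw, cont, setdiff(seq_len(n), i))
    } else X
    fold_fits[[j]] <- tryCatch(fit_fold(Xi, y, i, config),
                               error = function(e) {
                                 stop("fold ", i, " (patient ",
                                      cohort$data$patient_id[i], "): ",
                                      conditionMessage(e))
                               })
    if (config$verbose && j %% 20 == 0) {
      message("fold ", j, "/", length(folds))
    }
  }
  rk <- as.character(config$ratios)
  pred <- data.frame(patient_id = cohort$data$patient_id[folds],
                     true_label = y[folds])
  for (r in rk) {
    pred[[paste0("class_ratio", r)]] <-
      vapply(fold_fits, function(f) f$votes[[r]]$class, 0L)
    pred[[paste0("score_ratio", r)]] <-
      vapply(fold_fits, function(f) f$votes[[r]]$score, 0)
  }
  pred$final_score <- vapply(fold_fits, function(f) f$final_score, 0)
  run <- list(
    predictions = pred,
    folds = folds,
    n_vote_ties = sum(vapply(fold_fits, function(f) {
      sum(vapply(f$votes, function(v) v$tie, TRUE))
    }, 0)),
    config = config,
    schema = cohort$schema,
    X_raw = X_raw,
    y = y,
    artifacts = if (config$keep_artifacts) {
      list(masks = lapply(fold_fits, `[[`, "masks"),
           plans = lapply(fold_fits, `[[`, "plans"),
           sel = lapply(fold_fits, `[[`, "sel"),
           X = if (config$standardize_mode == "train-only") X_raw else X)
    }
  )
  class(run) <- "loo_run"
  run
}

#' @export
print.loo_run <- function(x, ...) {
  cat(sprintf("loo_run: %d folds x %d ratios x %d models (seed %d, %s standardization)\n",
              nrow(x$predictions), length(x$config$ratios),
              x$config$n_models, x$config$seed, x$config$standardize_mode))
  cat(sprintf("  vote ties resolved to rare class: %d\n", x$n_vote_ties))
  invisible(x)
}
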