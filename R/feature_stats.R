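#' Feature selection frequency across sub-model training sets
#'
#' For each ratio, the percentage of all training sets (pooled over
#' leave-one-out folds and sub-models) in which each feature passed the Gini
#' median rule.
#'
#' @param run A `loo_run` with artifacts.
#' @return A data.frame of class `frequency_table`: `feature, ratio,
#'   selection_pct, n_sets`.
#' @export
selection_frequency <- function(run) {
  if (!inherits(run, "loo_run")) stop("not a loo_run")
  if (is.null(run$artifacts)) {
    stop("run has no artifacts; rerun loo_predict with keep_artifacts = TRUE")
  }
  rows <- list()
  for (r in as.character(run$config$ratios)) {
    M <- do.call(rbind, lapply(run$artifacts$masks, `[[`, r))
    stopifnot(nrow(M) == nrow(run$predictions) * run$config$n_models)
    rows[[r]] <- data.frame(feature = colnames(M), ratio = as.integer(r),
                            selection_pct = 100 * colMeans(M),
                            n_sets = nrow(M), row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Univariate class-association tests
#'
#' Continuous and count features are compared between classes by the
#' Wilcoxon-Mann-Whitney rank-sum test (normal approximation with tie
#' correction, no continuity correction); binary features by Pearson's
#' chi-square test on the 2x2 class-by-level table without continuity
#' correction. A feature with a single observed level gets p = 1 by convention
#' and is flagged; a chi-square table with an expected cell count below 1 is
#' flagged but still tested (no automatic switch to an exact test).
#'
#' @param X Numeric feature matrix of one training set.
#' @param y Binary labels (1 = rare), both classes present.
#' @param kinds Named character vector of feature kinds (see
#'   [default_schema()]).
#' @return A data.frame `feature, test, p_value, degenerate, small_expected`.
#' @export
univariate_tests <- function(X, y, kinds) {
  if (length(unique(y)) < 2) stop("both classes must be present")
  res <- lapply(colnames(X), function(f) {
    x <- X[, f]
    out <- data.frame(feature = f, test = NA_character_, p_value = 1,
                      degenerate = FALSE, small_expected = FALSE)
    if (length(unique(x)) < 2) {
      out$degenerate <- TRUE
      out$test <- if (kinds[[f]] == "binary") "chisq" else "ranksum"
      return(out)  # p = 1 by convention
    }
    if (kinds[[f]] == "binary") {
      tab <- table(factor(x, levels = sort(unique(x))), factor(y, levels = c(0, 1)))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      out$small_expected <- any(expected < 1)
      out$p_value <- suppressWarnings(
        stats::chisq.test(tab, correct = FALSE)$p.value)
      out$test <- "chisq"
    } else {
      out$p_value <- suppressWarnings(
        stats::wilcox.test(x[y == 1], x[y == 0], exact = FALSE,
                           correct = FALSE)$p.value)
      out$test <- "ranksum"
    }
    if (is.na(out$p_value)) {
      out$p_value <- 1
      out$degenerate <- TRUE
    }
    out
  })
  do.call(rbind, res)
}

#' Univariate significance frequency across sub-model training sets
#'
#' For each ratio, the percentage of training sets in which each feature's
#' univariate test (see [univariate_tests()]) gives p < `alpha`. No
#' multiple-testing correction is applied (raw p-values, as published).
#' Because consecutive training sets share most of their rows, `n_sets` can
#' subsample the pooled sets to bound compute; the subsample is deterministic
#' given `seed`.
#'
#' @param run A `loo_run` with artifacts.
#' @param alpha Significance level (default 0.1).
#' @param n_sets Optional cap on the number of training sets tested per ratio.
#' @param seed Seed for the subsample when `n_sets` is given.
#' @return A data.frame of class `frequency_table`: `feature, ratio,
#'   significance_pct, n_sets`.
#' @export
significance_frequency <- function(run, alpha = 0.1, n_sets = NULL,
                                   seed = 1L) {
  if (!inherits(run, "loo_run")) stop("not a loo_run")
  if (is.null(run$artifacts)) {
    stop("run has no artifacts; rerun loo_predict with keep_artifacts = TRUE")
  }
  kinds <- feature_kinds(run$schema)
  X <- run$artifacts$X
  rows <- list()
  for (r in as.character(run$config$ratios)) {
    sets <- unlist(lapply(run$artifacts$plans, `[[`, r), recursive = FALSE)
    if (!is.null(n_sets) && n_sets < length(sets)) {
      set.seed(seed)
      sets <- sets[sort(sample.int(length(sets), n_sets))]
    }
    hits <- matrix(0, length(sets), ncol(X), dimnames = list(NULL, colnames(X)))
    for (s in seq_along(sets)) {
      idx <- sets[[s]]
      p <- univariate_tests(X[idx, , drop = FALSE], run$y[idx], kinds)
      hits[s, p$feature] <- as.integer(p$p_value < alpha)
    }
    rows[[r]] <- data.frame(feature = colnames(X), ratio = as.integer(r),
                            significance_pct = 100 * colMeans(hits),
                            n_sets = length(sets), row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("frequency_table", "data.frame")
  out
}
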