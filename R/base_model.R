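#' Gini-importance feature selection
#'
#' Fits a Random Forest (default 100 trees) and scores every feature by its
#' Gini-impurity decrease, normalized to sum 1. A feature is retained when its
#' normalized importance is strictly greater than the median importance over
#' all features; if the strict rule empties the mask (all importances equal,
#' e.g. all-constant features), the mask falls back to all features and a
#' warning is emitted.
#'
#' @param X Numeric training matrix (patients x features, named columns).
#' @param y Binary labels (1 = rare class).
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed for the forest.
#' @return List with `selected` (named logical mask) and `importances`
#'   (named, non-negative, sums to 1).
#' @export
select_features <- function(X, y, n_trees = 100L, seed = 1L) {
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (ncol(X) < 2) stop("feature selection needs at least 2 features")
  if (is.null(colnames(X))) stop("X must have column names")
  rf <- ranger::ranger(x = X, y = factor(y, levels = c("1", "0")),
                       num.trees = n_trees, importance = "impurity",
                       num.threads = 1, seed = seed)
  imp <- rf$variable.importance
  tot <- sum(imp)
  if (tot > 0) {
    imp <- imp / tot
  } else {
    imp <- rep(1 / length(imp), length(imp))
    names(imp) <- colnames(X)
  }
  mask <- imp > stats::median(imp)
  if (!any(mask)) {
    warning("all importances equal; falling back to the full feature set")
    mask[] <- TRUE
  }
  list(selected = mask, importances = imp)
}

# Platt-style sigmoid calibration: fit score = plogis(a * margin + b) on the
# training margins by Newton iteration with the regularized targets
# (n1 + 1)/(n1 + 2) and 1/(n0 + 2), which keep the optimum finite even on
# separable data.
platt_calibrate <- function(margins, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  t <- ifelse(y == 1, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  a <- 0
  b <- stats::qlogis(mean(t))
  for (it in 1:100) {
    p <- stats::plogis(a * margins + b)
    g <- c(sum((p - t) * margins), sum(p - t))
    w <- p * (1 - p)
    h11 <- sum(w * margins^2) + 1e-12
    h12 <- sum(w * margins)
    h22 <- sum(w) + 1e-12
    det <- h11 * h22 - h12 * h12
    step <- c(h22 * g[1] - h12 * g[2], h11 * g[2] - h12 * g[1]) / det
    a <- a - step[1]
    b <- b - step[2]
    if (max(abs(step)) < 1e-10) break
  }
  c(slope = a, offset = b)
}

# Linear SVM + Platt calibration on already-selected columns. The margin is
# explicitly oriented so that positive = rare class (libsvm's decision-value
# sign follows label order of appearance, which is not stable).
svm_platt_fit <- function(X, y, cost = 1, tol = 1e-4) {
  if (any(!is.finite(X))) stop("non-finite feature values in training matrix")
  fit <- e1071::svm(x = X, y = factor(y, levels = c("1", "0")),
                    kernel = "linear", cost = cost, scale = FALSE,
                    tolerance = tol)
  w <- stats::setNames(as.vector(crossprod(fit$coefs, fit$SV)), colnames(X))
  b <- -fit$rho
  m <- drop(X %*% w) + b
  if (mean(m[y == 1]) < mean(m[y == 0])) {  # orient toward the rare class
    w <- -w
    b <- -b
    m <- -m
  }
  calib <- platt_calibrate(m, y)
  list(weights = w, intercept = b, calibration = calib)
}

#' Fit a calibrated linear SVM and score a test instance
#'
#' Fits a soft-margin linear SVM (regularization `cost`, default 1) on the
#' given training matrix — which must already be restricted to the selected
#' features — and maps the signed margin to a [0,1] classification score by a
#' Platt-style logistic calibration fitted on the training margins. Scores
#' above 0.5 mean the rare class is predicted; the score is a strictly
#' increasing function of the margin whenever the calibration slope is
#' positive (the usual case; a zero slope can only arise from degenerate
#' constant margins).
#'
#' @param X_train Numeric training matrix restricted to selected features.
#' @param y_train Binary labels, both classes present (1 = rare).
#' @param x_test Numeric feature vector for the held-out instance.
#' @param cost SVM regularization constant C.
#' @param tol SVM solver tolerance.
#' @param seed Stored on the fit for provenance (the solver is deterministic).
#' @return List with `score` in [0,1] and `fit` (a `base_model_fit`).
#' @export
fit_score <- function(X_train, y_train, x_test, cost = 1, tol = 1e-4,
                      seed = 1L) {
  if (length(unique(y_train)) < 2) stop("training labels contain a single class")
  if (any(!is.finite(x_test))) stop("non-finite feature values in test vector")
  core <- svm_platt_fit(X_train, y_train, cost = cost, tol = tol)
  fit <- new_base_model_fit(
    selected = stats::setNames(rep(TRUE, ncol(X_train)), colnames(X_train)),
    importances = stats::setNames(rep(1 / ncol(X_train), ncol(X_train)),
                                  colnames(X_train)),
    weights = core$weights, intercept = core$intercept,
    calibration = core$calibration, seed = seed)
  list(score = predict_score(fit, x_test), fit = fit)
}

# Full backbone shared by every sub-model: Gini selection on all features,
# then a calibrated linear SVM on the retained ones. Weights are stored
# full-length with exact zeros for unselected features.
fit_base_model <- function(X, y, n_trees = 100L, cost = 1, tol = 1e-4,
                           seed = 1L) {
  sel <- select_features(X, y, n_trees = n_trees, seed = seed)
  core <- svm_platt_fit(X[, sel$selected, drop = FALSE], y,
                        cost = cost, tol = tol)
  w <- stats::setNames(numeric(ncol(X)), colnames(X))
  w[names(core$weights)] <- core$weights
  new_base_model_fit(selected = sel$selected, importances = sel$importances,
                     weights = w, intercept = core$intercept,
                     calibration = core$calibration, seed = seed)
}

new_base_model_fit <- function(selected, importances, weights, intercept,
                               calibration, seed) {
  structure(list(selected = selected, importances = importances,
                 weights = weights, intercept = intercept,
                 calibration = calibration, seed = as.integer(seed)),
            class = "base_model_fit")
}

#' Margin of a fitted base model
#' @param fit A `base_model_fit`.
#' @param x Feature vector covering the fit's features.
#' @return The signed SVM margin (positive = rare side).
#' @export
predict_margin <- function(fit, x) {
  f <- names(fit$weights)
  xv <- if (is.null(names(x))) x[seq_along(fit$weights)] else x[f]
  sum(fit$weights * xv) + fit$intercept
}

#' Calibrated [0,1] score of a fitted base model
#' @inheritParams predict_margin
#' @return Score in [0,1]; > 0.5 predicts the rare class.
#' @export
predict_score <- function(fit, x) {
  m <- predict_margin(fit, x)
  unname(stats::plogis(fit$calibration["slope"] * m + fit$calibration["offset"]))
}

#' @export
print.base_model_fit <- function(x, ...) {
  cat(sprintf("base_model_fit: %d/%d features selected; calibration slope %.3f\n",
              sum(x$selected), length(x$selected), x$calibration["slope"]))
  invisible(x)
}
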