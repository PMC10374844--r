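test_that("trapezoidal AUC matches hand-counted concordance on worked examples", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.2), c(1, 1, 0, 0))$auc, 1)
  # rare {0.9, 0.4}, abundant {0.8, 0.1, 0.2}: 5 concordant pairs of 6
  scores <- c(0.9, 0.4, 0.8, 0.1, 0.2)
  labels <- c(1, 1, 0, 0, 0)
  expect_equal(roc_auc(scores, labels)$auc, 5 / 6)
  expect_equal(concordance_auc(scores, labels), 5 / 6)
  # a tie contributes one half
  expect_equal(roc_auc(c(0.5, 0.5), c(1, 0))$auc, 0.5)
})

test_that("trapezoidal AUC equals the concordance statistic on random tied data", {
  set.seed(13)
  for (k in 1:60) {
    n <- sample(5:50, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), 1)  # heavy ties
    expect_equal(roc_auc(scores, labels)$auc, concordance_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(14)
  for (k in 1:10) {
    n <- 40
    labels <- c(1, 0, rbinom(n - 2, 1, 0.3))
    scores <- round(runif(n), 2)
    expect_equal(roc_auc(scores, labels)$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                quiet = TRUE, direction = "<"))),
                 tolerance = 1e-10)
  }
})

test_that("the ROC curve is monotone and spans both corners", {
  set.seed(15)
  scores <- runif(30); labels <- rbinom(30, 1, 0.5); labels[1:2] <- c(0, 1)
  roc <- roc_auc(scores, labels)
  p <- roc$points
  expect_true(all(diff(p$sensitivity) <= 0))  # non-increasing with threshold
  expect_true(all(diff(p$specificity) >= 0))
  expect_equal(p$sensitivity[1], 1)
  expect_equal(p$specificity[1], 0)
  expect_equal(p$sensitivity[nrow(p)], 0)
  expect_equal(p$specificity[nrow(p)], 1)
})

test_that("youden_threshold matches an exhaustive scan and favors sensitivity on ties", {
  set.seed(16)
  for (k in 1:50) {
    n <- sample(6:40, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.3))
    scores <- round(runif(n), 1)
    roc <- roc_auc(scores, labels)
    # random instances occasionally have max J = 0 (degenerate warning)
    expect_equal(suppressWarnings(youden_threshold(roc)),
                 youden_scan_oracle(scores, labels))
  }
  # perfect separation: the midpoint of the gap attains J = 1
  thr <- youden_threshold(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)))
  expect_equal(thr, 0.55)
  # constant scores: degenerate, J = 0 everywhere
  expect_warning(youden_threshold(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 0, 0))),
                 "degenerate")
})

test_that("confusion metrics follow the printed formulas", {
  m <- confusion_metrics(c(0.9, 0.1), c(1, 0), 0.5)
  expect_equal(m$tp, 1); expect_equal(m$tn, 1)
  expect_equal(m$accuracy, 1); expect_equal(m$gmean, 1); expect_equal(m$auc, 1)

  # hand-counted table: TP=2, FN=2, TN=6, FP=2 at threshold 0.5
  scores <- c(0.9, 0.8, 0.2, 0.1,  0.7, 0.6, rep(0.3, 6))
  labels <- c(1, 1, 1, 1,  0, 0, rep(0, 6))
  m <- confusion_metrics(scores, labels, 0.5)
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(2, 2, 6, 2))
  expect_equal(m$accuracy, 8 / 12)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$gmean, sqrt(0.375))
  # a score exactly at the threshold goes to the abundant class (strict >)
  m2 <- confusion_metrics(c(0.5, 0.6), c(1, 0), 0.5)
  expect_equal(m2$fn, 1)
  expect_error(confusion_metrics(scores, labels, Inf), "finite")
})

test_that("metric identities hold on random reports", {
  set.seed(17)
  for (k in 1:30) {
    n <- sample(8:60, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.3))
    scores <- runif(n)
    m <- confusion_metrics(scores, labels, runif(1))
    expect_equal(m$tp + m$tn + m$fp + m$fn, n)
    expect_lt(abs(m$gmean^2 - m$sensitivity * m$specificity), 1e-12)
    P <- sum(labels == 1); N <- n - P
    expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N))
  }
})

test_that("scores independent of labels give AUC near one half on average", {
  set.seed(18)
  aucs <- replicate(200, {
    labels <- rep(0, 184); labels[sample(184, 14)] <- 1
    roc_auc(runif(184), labels)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("the single-model baseline is near-perfect on balanced separable data", {
  set.seed(19)
  n <- 20
  y <- rep(c(1, 0), each = n / 2)
  age <- rnorm(n, ifelse(y == 1, 70, 40), 2)
  co <- mini_cohort(age = age, bmi = rnorm(n, 24, 2),
                    paps = rbinom(n, 1, 0.5), nrel = rbinom(n, 3, 0.2),
                    outcome = y)
  base <- original_model_baseline(co, run_config(seed = 1, n_trees = 50))
  expect_gt(base$auc, 0.95)
})

test_that("under-sampling beats the single-model baseline on imbalanced signal", {
  # paired seeds: moderate planted signal, 14% prevalence
  wins <- 0
  for (s in 1:5) {
    co <- generate_cohort(mini_gen_config(n = 36, n_rare = 5,
                                          effects = c(Age = 1.2), seed = s))
    cfg <- run_config(seed = s, n_models = 4, n_trees = 50,
                      keep_artifacts = FALSE)
    ens <- evaluate_run(loo_predict(co, cfg))
    base <- original_model_baseline(co, cfg)
    wins <- wins + (ens$auc > base$auc)
  }
  expect_gte(wins, 3)
})
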