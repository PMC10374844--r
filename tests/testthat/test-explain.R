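test_that("margin-space contributions follow the closed form w_i * (x_i - mu_i)", {
  w <- c(a = 1, b = -1)
  fit <- make_fit(w)
  bg <- matrix(c(0, 2, 1, 3, -1, 1), 3, 2, byrow = TRUE,
               dimnames = list(NULL, c("a", "b")))  # column means (0, 2)
  x <- c(a = 2, b = 3)  # x - mu = (2, 1)
  ex <- linear_shap(fit, x, bg)
  expect_equal(unname(ex$margin_contributions), c(2, -1))
})

test_that("a patient at the background mean has zero contributions and base score", {
  set.seed(20)
  d <- separable_xy(n_per_class = 10, gap = 2, p_noise = 2, seed = 20)
  fit <- fit_score(d$X, d$y, d$X[1, ])$fit
  mu <- colMeans(d$X)
  ex <- linear_shap(fit, mu, d$X)
  expect_equal(unname(ex$contributions), rep(0, 3))
  expect_equal(ex$score, ex$base_value)
})

test_that("additivity holds in score and margin space for random instances", {
  set.seed(21)
  d <- separable_xy(n_per_class = 12, gap = 1.5, p_noise = 3, seed = 21)
  fit <- fit_score(d$X, d$y, d$X[1, ])$fit
  for (k in 1:100) {
    x <- rnorm(4); names(x) <- colnames(d$X)
    ex <- linear_shap(fit, x, d$X)
    expect_lt(abs(ex$base_value + sum(ex$contributions) - ex$score), 1e-6)
    expect_lt(abs(ex$base_margin + sum(ex$margin_contributions) -
                  predict_margin(fit, x)), 1e-9)
  }
})

test_that("the closed form equals full coalition enumeration of the margin game", {
  set.seed(22)
  for (k in 1:10) {
    p <- sample(2:4, 1)
    w <- setNames(rnorm(p), paste0("f", 1:p))
    fit <- make_fit(w, intercept = rnorm(1))
    bg <- matrix(rnorm(20 * p), 20, p, dimnames = list(NULL, names(w)))
    x <- setNames(rnorm(p), names(w))
    mu <- colMeans(bg)
    # value of a coalition: margin with absent features at their background mean
    value <- function(S) {
      xv <- mu
      xv[S] <- x[S]
      sum(w * xv) + fit$intercept
    }
    ex <- linear_shap(fit, x, bg)
    expect_equal(unname(ex$margin_contributions),
                 shapley_enum(value, p), tolerance = 1e-10)
  }
})

test_that("features outside the selected mask contribute exactly zero", {
  set.seed(23)
  n <- 40
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- rep(c(1, 0), each = n / 2)
  X[, 1] <- X[, 1] + 2 * y
  fit <- rrsorisk:::fit_base_model(X, y, n_trees = 50, seed = 3)
  expect_true(any(!fit$selected))
  x <- rnorm(6); names(x) <- colnames(X)
  ex <- linear_shap(fit, x, X)
  expect_true(all(ex$contributions[!fit$selected] == 0))
  expect_true(all(ex$margin_contributions[!fit$selected] == 0))
})

test_that("ensemble averaging cancels opposite-sign contributions and keeps additivity", {
  w1 <- c(a = 1, b = 0.5); w2 <- c(a = 0, b = 0.5); w3 <- c(a = -1, b = 0.5)
  bg <- matrix(c(0, 0, 0, 2), 2, 2, dimnames = list(NULL, c("a", "b")))
  x <- c(a = 1, b = 2)
  exs <- lapply(list(w1, w2, w3), function(w) {
    linear_shap(make_fit(w), x, bg)
  })
  ens <- explain_ensemble(exs)
  # margin contributions of "a": +1, 0, -1 across ratios -> 0 in the ensemble
  expect_equal(unname(Reduce(`+`, lapply(exs, function(e)
    e$margin_contributions["a"])) / 3), 0)
  expect_equal(ens$score, mean(vapply(exs, `[[`, 0, "score")))
  expect_lt(abs(ens$base_value + sum(ens$contributions) - ens$score), 1e-6)
  # identical explanations average to themselves
  same <- explain_ensemble(list(exs[[1]], exs[[1]], exs[[1]]))
  expect_equal(same$contributions, exs[[1]]$contributions)
  expect_equal(same$score, exs[[1]]$score)
})

test_that("explain_patient reproduces the vote scores and stays additive at all levels", {
  co <- generate_cohort(mini_gen_config(n = 28, n_rare = 6, seed = 12))
  cfg <- run_config(seed = 5, n_models = 4, n_trees = 25)
  run <- loo_predict(co, cfg, folds = c(1, 2, 9))
  for (pid in run$predictions$patient_id) {
    ex <- explain_patient(run, pid)
    i <- match(pid, run$predictions$patient_id)
    for (r in 1:3) {
      e <- ex[[paste0("ratio", r)]]
      expect_equal(e$score, run$predictions[[paste0("score_ratio", r)]][i])
      expect_lt(abs(e$base_value + sum(e$contributions) - e$score), 1e-6)
    }
    expect_equal(ex$ensemble$score, run$predictions$final_score[i])
    expect_lt(abs(ex$ensemble$base_value + sum(ex$ensemble$contributions) -
                  ex$ensemble$score), 1e-6)
    expect_setequal(ex$table$feature, mini_schema()$name)
  }
})

test_that("which sub-model holds the vote score determines the explanation", {
  bg <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  x <- c(a = 1.2, b = -0.4)
  fit_hi <- make_fit(c(a = 2, b = 0), slope = 1.5)
  fit_lo <- make_fit(c(a = 0, b = 1), slope = 1.5)
  s_hi <- predict_score(fit_hi, x); s_lo <- predict_score(fit_lo, x)
  vote <- majority_vote(classes = c(1, 1), scores = c(s_hi, s_lo))
  picked <- list(fit_hi, fit_lo)[[vote$model_index]]
  ex <- explain_ratio(vote, picked, x, bg)
  expect_equal(ex$score, vote$score)
  # the alternative model would have yielded a different attribution
  other <- linear_shap(list(fit_hi, fit_lo)[[3 - vote$model_index]], x, bg)
  expect_false(isTRUE(all.equal(ex$contributions, other$contributions)))
})

test_that("mean-over-models explanations require kept fits and stay additive", {
  co <- generate_cohort(mini_gen_config(n = 18, n_rare = 4, seed = 14))
  cfg <- run_config(seed = 2, n_models = 3, n_trees = 25)
  run <- loo_predict(co, cfg, folds = 1)
  expect_error(explain_patient(run, 1, method = "mean-over-models"),
               "keep_all_fits")
  cfg2 <- run_config(seed = 2, n_models = 3, n_trees = 25, keep_all_fits = TRUE)
  run2 <- loo_predict(co, cfg2, folds = 1)
  ex <- explain_patient(run2, 1, method = "mean-over-models")
  e <- ex$ratio1
  expect_lt(abs(e$base_value + sum(e$contributions) - e$score), 1e-6)
})
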