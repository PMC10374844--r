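test_that("resampling plans honour the exact 1:r arithmetic", {
  y <- rep(c(1, 0), c(14, 150))
  plan <- make_training_sets(y, ratio = 3, n_models = 20, seed = 1)
  expect_equal(length(plan$rare), 14)
  for (s in plan$abundant_sets) {
    expect_equal(length(s), 42)                    # 3 x 14
    expect_equal(length(unique(s)), 42)            # without replacement
    expect_true(all(y[s] == 0))
    expect_equal(length(plan$rare) + length(s), 56)
  }
  # draws differ across models (almost surely for 150-choose-42)
  expect_gt(length(unique(plan$abundant_sets)), 1)
  # reproducibility
  plan2 <- make_training_sets(y, ratio = 3, n_models = 20, seed = 1)
  expect_identical(plan, plan2)
})

test_that("a pool exactly matching the ratio forces identical sets with a warning", {
  y <- rep(c(1, 0), c(5, 5))
  expect_warning(plan <- make_training_sets(y, ratio = 1, n_models = 4, seed = 2),
                 "identical")
  expect_equal(length(unique(plan$abundant_sets)), 1)
  expect_error(make_training_sets(y, ratio = 2, n_models = 4, seed = 2),
               "ratio 1:2")
})

test_that("majority_vote follows the modal class and max/min score rule", {
  v <- majority_vote(classes = c(1, 1, 0), scores = c(0.9, 0.6, 0.2))
  expect_equal(v$class, 1)
  expect_equal(v$score, 0.9)
  v <- majority_vote(classes = c(0, 0, 1), scores = c(0.4, 0.1, 0.8))
  expect_equal(v$class, 0)
  expect_equal(v$score, 0.1)
  v <- majority_vote(classes = rep(1, 100), scores = rep(0.73, 100))
  expect_equal(v$class, 1)
  expect_equal(v$score, 0.73)
  expect_false(v$tie)
  # 50/50 tie resolves to the rare class and is flagged
  v <- majority_vote(classes = c(1, 0), scores = c(0.55, 0.45))
  expect_equal(v$class, 1)
  expect_true(v$tie)
  expect_error(majority_vote(integer(), numeric()), "empty")
  expect_error(majority_vote(c(1, 0), c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("majority_vote matches a brute-force oracle on random vote lists", {
  set.seed(10)
  for (k in 1:100) {
    n <- sample(1:25, 1)
    cl <- rbinom(n, 1, 0.5)
    if (all(cl == 1)) cl[1] <- 0L else if (all(cl == 0)) cl[1] <- 1L
    sc <- round(runif(n), 2)
    got <- majority_vote(cl, sc)
    want <- vote_oracle(cl, sc)
    expect_equal(got$class, want$class)
    expect_equal(got$score, want$score)
    expect_equal(got$classes[got$model_index], got$class)
  }
})

test_that("raising the aggregated model's score never lowers a rare-class vote score", {
  cl <- c(1, 1, 1, 0)
  sc <- c(0.8, 0.6, 0.7, 0.2)
  v0 <- majority_vote(cl, sc)
  sc[v0$model_index] <- min(1, sc[v0$model_index] + 0.1)
  v1 <- majority_vote(cl, sc)
  expect_gte(v1$score, v0$score)
})

test_that("soft_vote is the plain arithmetic mean", {
  expect_equal(soft_vote(c(0.62, 0.63, 0.70)), 0.65)
  expect_equal(round(soft_vote(c(0.15, 0.19, 0.24)), 2), 0.19)
  expect_equal(soft_vote(c(0.3, 0.3, 0.3)), 0.3)          # idempotent
  expect_equal(soft_vote(c(0.7, 0.1, 0.4)), soft_vote(c(0.4, 0.7, 0.1)))
  expect_error(soft_vote(c(0.5, 1.4)), "\\[0,1\\]")
})

test_that("leave-one-out runs are leakage-free with exact per-set class ratios", {
  co <- generate_cohort(mini_gen_config(n = 28, n_rare = 6, seed = 4))
  cfg <- run_config(seed = 2, n_models = 4, n_trees = 25,
                    standardize_mode = "as-published")
  run <- loo_predict(co, cfg)
  expect_equal(nrow(run$predictions), 28)
  y <- co$data$outcome
  for (j in seq_along(run$folds)) {
    i <- run$folds[j]
    n_rare_pool <- sum(y[-i] == 1)
    for (r in c("1", "2", "3")) {
      for (rows in run$artifacts$plans[[j]][[r]]) {
        expect_false(i %in% rows)                        # no leakage
        expect_equal(sum(y[rows] == 1), n_rare_pool)     # all rare samples
        expect_equal(sum(y[rows] == 0), as.integer(r) * n_rare_pool)
      }
    }
  }
  # final score is the soft vote of the three ratio scores
  expect_equal(run$predictions$final_score,
               rowMeans(run$predictions[, c("score_ratio1", "score_ratio2",
                                            "score_ratio3")]))
  expect_true(all(run$predictions$final_score >=
                  pmin(run$predictions$score_ratio1,
                       run$predictions$score_ratio2,
                       run$predictions$score_ratio3)))
})

test_that("runs are reproducible and fold subsets match the full run", {
  co <- generate_cohort(mini_gen_config(n = 24, n_rare = 5, seed = 6))
  cfg <- run_config(seed = 9, n_models = 3, n_trees = 25)
  full1 <- loo_predict(co, cfg)
  full2 <- loo_predict(co, cfg)
  expect_identical(full1$predictions, full2$predictions)
  sub <- loo_predict(co, cfg, folds = c(3, 11, 17))
  expect_equal(sub$predictions,
               full1$predictions[c(3, 11, 17), ],
               ignore_attr = TRUE)
})

test_that("a single model per ratio degenerates to the soft vote of three scores", {
  co <- generate_cohort(mini_gen_config(n = 18, n_rare = 4, seed = 8))
  cfg <- run_config(seed = 1, n_models = 1, n_trees = 25)
  run <- loo_predict(co, cfg, folds = 1:4)
  p <- run$predictions
  expect_equal(p$final_score,
               (p$score_ratio1 + p$score_ratio2 + p$score_ratio3) / 3)
})

test_that("incomplete cohorts and single-class pools are rejected", {
  co <- mini_cohort(age = c(50, 30, NA, 40), bmi = c(24, 20, 21, 22))
  expect_error(loo_predict(co, run_config()), "impute_missing")
  co2 <- mini_cohort(age = c(50, 30, 45, 40), bmi = c(24, 20, 21, 22),
                     outcome = c(1, 0, 0, 0))
  expect_error(loo_predict(co2, run_config()), "at least 2")
})
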