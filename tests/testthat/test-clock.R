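make_age_data <- function(n, p, seed = 1, noise = 0.5) {
  set.seed(seed)
  age <- runif(n, 39, 71)
  X <- named_matrix(rnorm(n * p, 0, noise), n, p)
  for (j in seq_len(min(5, p))) X[, j] <- X[, j] + 0.05 * j * age
  list(X = X, age = age)
}

test_that("cohort splitting is disjoint, exhaustive and deterministic", {
  ids <- sprintf("S%05d", 1:100)
  sp <- split_cohort(ids, 0.70, seed = 3)
  expect_length(sp$train, 70)
  expect_length(sp$test, 30)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, split_cohort(ids, 0.70, seed = 3))
  expect_false(identical(sp, split_cohort(ids, 0.70, seed = 4)))
  expect_length(split_cohort(ids, 0.731, seed = 1)$train, 73)
  expect_error(split_cohort(c("a", "a", "b")), "unique")
  expect_error(split_cohort(ids, 1.2), "train_fraction")
})

test_that("folds partition the ids", {
  ids <- sprintf("S%05d", 1:53)
  folds <- protclock:::make_folds(ids, 5, seed = 2)
  expect_length(folds, 5)
  expect_setequal(unlist(folds), ids)
  expect_equal(anyDuplicated(unlist(folds)), 0)
})

test_that("age gap is predicted minus chronological age, aligned by id", {
  pred <- c(S2 = 50, S1 = 60)
  age <- c(S1 = 55, S2 = 52)
  g <- compute_age_gap(pred, age)
  expect_equal(g$gap[g$sample_id == "S1"], 5)
  expect_equal(g$gap[g$sample_id == "S2"], -2)
  expect_error(compute_age_gap(c(a = 1), c(b = 1)), "ids")
})

test_that("prediction metrics match their definitions", {
  pred <- c(1, 2, 3, 5)
  act <- c(1, 2, 4, 4)
  m <- evaluate_predictions(pred, act)
  expect_equal(m$pearson_r, cor(pred, act))
  expect_equal(m$r_squared,
               1 - sum((pred - act)^2) / sum((act - mean(act))^2))
  expect_equal(m$rmse, sqrt(mean((pred - act)^2)))
  expect_equal(m$mae, mean(abs(pred - act)))
})

test_that("gap summaries report bands, deciles and the extreme-band contrast", {
  g <- compute_age_gap(setNames(1:100 + 0, sprintf("S%03d", 1:100)),
                       setNames(rep(0, 100), sprintf("S%03d", 1:100)))
  s <- summarize_gap(g, tail_fraction = 0.05)
  expect_equal(s$bands$n, c(5, 5))
  expect_equal(s$bands$mean_gap, c(3, 98))
  expect_equal(s$top_bottom_difference, 95)
  expect_equal(sum(s$deciles$n), 100)
  expect_equal(s$deciles$mean_gap[1], mean(1:10))
  expect_error(summarize_gap(g, tail_fraction = 0.6), "bands")
})

test_that("fit_clock validates inputs, stops early and predicts the holdout", {
  d <- make_age_data(400, 10, seed = 5, noise = 0.2)
  sp <- split_cohort(rownames(d$X), 0.7, 1)
  hp <- clock_hyperparams(n_estimators = 3000, seed = 2)
  m <- fit_clock(d$X[sp$train, ], d$age[match(sp$train, rownames(d$X))], hp,
                 d$X[sp$test, ], d$age[match(sp$test, rownames(d$X))])
  expect_s3_class(m, "clock_model")
  expect_lt(m$best_iter + 1, 3000)  # early stopping engaged
  expect_equal(length(m$trees$offset), m$best_iter + 1)
  pr <- predict(m, d$X[sp$test, ])
  met <- evaluate_predictions(pr, d$age[match(sp$test, rownames(d$X))])
  expect_gt(met$pearson_r, 0.9)
  expect_error(fit_clock(d$X[sp$train, ], d$age[match(sp$train, rownames(d$X))],
                         hp, d$X[sp$train[1:30], ], d$age[1:30]),
               "overlaps")
})

test_that("prediction matches column reordering but rejects missing proteins", {
  d <- make_age_data(200, 6, seed = 6)
  sp <- split_cohort(rownames(d$X), 0.7, 1)
  hp <- clock_hyperparams(seed = 1)
  m <- fit_clock(d$X[sp$train, ], d$age[match(sp$train, rownames(d$X))], hp,
                 d$X[sp$test, ], d$age[match(sp$test, rownames(d$X))])
  shuffled <- d$X[sp$test, rev(colnames(d$X))]
  expect_equal(predict(m, shuffled), predict(m, d$X[sp$test, ]))
  expect_error(predict(m, d$X[sp$test, 1:4]))
})

test_that("out-of-fold predictions come from models that never saw the sample", {
  d <- make_age_data(240, 8, seed = 7, noise = 0.3)
  hp <- clock_hyperparams(n_estimators = 300, seed = 1)
  res <- oof_predict_age(d$X, d$age, hp, k = 3, seed = 4,
                         return_models = TRUE)
  g <- res$gap
  expect_setequal(g$sample_id, rownames(d$X))
  expect_false(anyNA(g$predicted_age))
  expect_equal(g$gap, g$predicted_age - g$age)
  for (f in 1:3) {
    hold <- res$folds[[f]]
    expect_equal(sort(unique(g$fold[match(hold, g$sample_id)])), f)
    # fold training ids exclude the held-out fold entirely
    expect_length(intersect(res$models[[f]]$train_ids, hold), 0)
    # the gap table's predictions equal direct predict() of the fold model
    expect_equal(g$predicted_age[match(hold, g$sample_id)],
                 unname(predict(res$models[[f]], d$X[hold, , drop = FALSE])))
  }
  # determinism
  g2 <- oof_predict_age(d$X, d$age, hp, k = 3, seed = 4)
  expect_equal(g, g2)
})

test_that("importance ranking places most aging proteins above every null protein", {
  # uniformly strong slopes: with heterogeneous slopes the weakest aging
  # proteins are redundant given the strong ones and boosted trees ignore
  # them, so a ranking guarantee is only meaningful when each aging protein
  # carries comparable, detectable signal
  cfg <- synth_config(3000, 500, 50, noise_sd = 0.2, aging_rate_sd = 2,
                      missing_rate = 0, slopes = rep(0.08, 50), seed = 11)
  co <- generate_cohort(cfg)
  age <- setNames(co$phenotypes$age, co$phenotypes$sample_id)
  sp <- split_cohort(rownames(co$proteins), 0.70, 1)
  inner <- split_cohort(sp$train, 0.85, 2)
  m <- fit_clock(co$proteins[inner$train, ], age[inner$train],
                 clock_hyperparams(seed = 1),
                 co$proteins[inner$test, ], age[inner$test])
  imp <- shap_importance(m, co$proteins[sp$train, ])
  best_null <- max(imp[!co$truth$aging_flag])
  expect_gte(mean(imp[co$truth$aging_flag] > best_null), 0.80)
})

test_that("gap conservation: mean gap equals mean predicted age minus mean age", {
  set.seed(12)
  g <- compute_age_gap(setNames(rnorm(50, 55, 5), sprintf("S%03d", 1:50)),
                       setNames(rnorm(50, 55, 5), sprintf("S%03d", 1:50)))
  expect_equal(mean(g$gap), mean(g$predicted_age) - mean(g$age))
})

test_that("a saved clock reloads with identical predictions and attributions", {
  d <- make_age_data(200, 6, seed = 8)
  sp <- split_cohort(rownames(d$X), 0.7, 1)
  hp <- clock_hyperparams(seed = 3)
  m <- fit_clock(d$X[sp$train, ], d$age[match(sp$train, rownames(d$X))], hp,
                 d$X[sp$test, ], d$age[match(sp$test, rownames(d$X))])
  dir <- withr::local_tempdir()
  save_clock_model(m, dir)
  m2 <- load_clock_model(dir)
  Xt <- d$X[sp$test, ]
  expect_equal(predict(m2, Xt), predict(m, Xt))
  expect_equal(shap_values(m2, Xt), shap_values(m, Xt), tolerance = 1e-6)
  expect_identical(m2$proteins, m$proteins)
})

test_that("tuning always scores the default candidate and returns the CV winner", {
  d <- make_age_data(150, 6, seed = 9)
  hp <- tune_clock(d$X, d$age, trials = 3, k = 3, seed = 2,
                   n_estimators = 200)
  tr <- attr(hp, "trials")
  expect_equal(nrow(tr), 3)
  def <- clock_hyperparams()
  expect_equal(tr$eta[1], def$eta)
  expect_equal(tr$max_depth[1], def$max_depth)
  expect_equal(attr(hp, "cv_r2"), max(tr$cv_r2))
  expect_gte(attr(hp, "cv_r2"), tr$cv_r2[1])
})

test_that("benchmarks cover boosted, lasso and elastic-net models on every eval set", {
  d <- make_age_data(300, 8, seed = 10, noise = 0.2)
  sp <- split_cohort(rownames(d$X), 0.7, 1)
  tr_idx <- match(sp$train, rownames(d$X))
  te_idx <- match(sp$test, rownames(d$X))
  out <- benchmark_baselines(
    d$X[sp$train, ], d$age[tr_idx],
    eval_sets = list(test = list(X = d$X[sp$test, ], age = d$age[te_idx])),
    hyperparams = clock_hyperparams(n_estimators = 300), seed = 2)
  expect_setequal(out$model, c("gbm", "lasso", "elastic_net"))
  expect_equal(nrow(out), 3)
  # the signal here is linear, so every model should correlate strongly
  expect_true(all(out$pearson_r > 0.8))
})
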