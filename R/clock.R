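#' Hyperparameters for the boosted-tree age clock
#'
#' Estimator cap (5,000 boosting rounds) and early-stopping patience (20
#' rounds) follow the clock's training protocol; the remaining knobs define
#' the tuning search space documented in [tune_clock()].
#'
#' @param eta learning rate.
#' @param max_depth maximum tree depth.
#' @param min_child_weight minimum hessian sum per leaf.
#' @param subsample row subsampling fraction per round, in (0, 1].
#' @param colsample_bytree column subsampling fraction per tree, in (0, 1].
#' @param reg_alpha L1 regularization.
#' @param reg_lambda L2 regularization.
#' @param n_estimators boosting-round cap.
#' @param early_stopping_rounds patience for early stopping on the holdout.
#' @param seed booster seed (controls subsampling).
#' @export
clock_hyperparams <- function(eta = 0.05, max_depth = 4, min_child_weight = 1,
                              subsample = 0.8, colsample_bytree = 0.8,
                              reg_alpha = 0, reg_lambda = 1,
                              n_estimators = 5000, early_stopping_rounds = 20,
                              seed = 1L) {
  check_number(eta, "eta", lo = 1e-6, hi = 1)
  check_number(max_depth, "max_depth", lo = 1)
  check_number(subsample, "subsample", lo = 1e-6, hi = 1)
  check_number(colsample_bytree, "colsample_bytree", lo = 1e-6, hi = 1)
  check_number(reg_alpha, "reg_alpha", lo = 0)
  check_number(reg_lambda, "reg_lambda", lo = 0)
  check_number(n_estimators, "n_estimators", lo = 1)
  check_number(early_stopping_rounds, "early_stopping_rounds", lo = 1)
  structure(list(eta = eta, max_depth = as.integer(max_depth),
                 min_child_weight = min_child_weight, subsample = subsample,
                 colsample_bytree = colsample_bytree, reg_alpha = reg_alpha,
                 reg_lambda = reg_lambda,
                 n_estimators = as.integer(n_estimators),
                 early_stopping_rounds = as.integer(early_stopping_rounds),
                 seed = as.integer(seed)),
            class = "clock_hyperparams")
}

xgb_params <- function(hp) {
  list(objective = "reg:squarederror", eta = hp$eta, max_depth = hp$max_depth,
       min_child_weight = hp$min_child_weight, subsample = hp$subsample,
       colsample_bytree = hp$colsample_bytree, alpha = hp$reg_alpha,
       lambda = hp$reg_lambda, nthread = 1, seed = hp$seed,
       tree_method = "hist")
}

# Core booster fit. With an eval set, stops early on holdout RMSE (on a fixed
# holdout, minimizing RMSE selects the same round as maximizing R^2, since
# R^2 = 1 - MSE / var(y)). Without one, runs a fixed number of rounds.
fit_gbm <- function(X, y, hp, eval = NULL, nrounds = NULL) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  if (is.null(eval)) {
    if (is.null(nrounds)) fail("`nrounds` required when no eval set is given")
    booster <- xgboost::xgb.train(xgb_params(hp), dtrain,
                                  nrounds = nrounds, verbose = 0)
  } else {
    deval <- xgboost::xgb.DMatrix(eval$X, label = eval$y)
    booster <- xgboost::xgb.train(
      xgb_params(hp), dtrain, nrounds = hp$n_estimators,
      evals = list(eval = deval),
      early_stopping_rounds = hp$early_stopping_rounds, verbose = 0)
  }
  booster
}

#' Split sample ids into train and test sets
#'
#' @param sample_ids character vector of unique ids.
#' @param train_fraction fraction assigned to training (default 70:30).
#' @param seed RNG seed; identical seeds give identical splits.
#' @return list with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
split_cohort <- function(sample_ids, train_fraction = 0.70, seed = 1L) {
  if (anyDuplicated(sample_ids)) fail("`sample_ids` must be unique")
  n <- length(sample_ids)
  if (n < 10) fail("need at least 10 samples to split")
  if (!is.finite(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    fail("`train_fraction` must be in (0, 1)")
  }
  set.seed(seed)
  n_train <- floor(train_fraction * n + 0.5)
  train <- sort(sample(sample_ids, n_train))
  list(train = train, test = sort(setdiff(sample_ids, train)))
}

make_folds <- function(ids, k, seed) {
  if (k < 2) fail("`k` must be at least 2")
  if (length(ids) < k) fail("fewer samples than folds")
  set.seed(seed)
  shuffled <- sample(ids)
  fold <- rep_len(seq_len(k), length(ids))
  split(shuffled, fold)
}

#' Tune clock hyperparameters by random search over k-fold CV R-squared
#'
#' Samples `trials` candidates (the first is always the default
#' [clock_hyperparams()], so tuning never falls below the default's CV
#' performance) from the documented space: eta log-uniform on
#' \[0.01, 0.3\], max_depth uniform on 2..8, min_child_weight log-uniform on
#' \[1, 50\], subsample on \[0.5, 1\], colsample_bytree on \[0.3, 1\],
#' reg_alpha log-uniform on \[1e-3, 10\], reg_lambda log-uniform on
#' \[1e-2, 10\]. Each candidate is scored by mean k-fold R-squared; within
#' each fold the held-out part doubles as the early-stopping set.
#'
#' @param X complete samples-by-proteins training matrix.
#' @param age chronological ages aligned with `X` rows.
#' @param trials number of sampled candidates (>= 1).
#' @param k folds.
#' @param seed RNG seed for candidate sampling and fold assignment.
#' @param n_estimators,early_stopping_rounds passed to every candidate.
#' @return the winning `clock_hyperparams`, with attributes `cv_r2` (its mean
#'   CV R-squared) and `trials` (data.frame of all candidates and scores).
#' @export
tune_clock <- function(X, age, trials = 200, k = 5, seed = 1L,
                       n_estimators = 5000, early_stopping_rounds = 20) {
  check_protein_matrix(X, allow_missing = FALSE)
  if (trials < 1) fail("`trials` must be at least 1")
  folds <- make_folds(rownames(X), k, derive_seed(seed, "tune"))
  set.seed(seed)
  cands <- vector("list", trials)
  cands[[1]] <- clock_hyperparams(n_estimators = n_estimators,
                                  early_stopping_rounds = early_stopping_rounds,
                                  seed = seed)
  if (trials > 1) {
    for (t in 2:trials) {
      cands[[t]] <- clock_hyperparams(
        eta = exp(runif(1, log(0.01), log(0.3))),
        max_depth = sample(2:8, 1),
        min_child_weight = exp(runif(1, log(1), log(50))),
        subsample = runif(1, 0.5, 1),
        colsample_bytree = runif(1, 0.3, 1),
        reg_alpha = exp(runif(1, log(1e-3), log(10))),
        reg_lambda = exp(runif(1, log(1e-2), log(10))),
        n_estimators = n_estimators,
        early_stopping_rounds = early_stopping_rounds, seed = seed)
    }
  }
  scores <- vapply(cands, function(hp) {
    mean(vapply(folds, function(hold) {
      tr <- setdiff(rownames(X), hold)
      b <- fit_gbm(X[tr, , drop = FALSE], age[match(tr, rownames(X))], hp,
                   eval = list(X = X[hold, , drop = FALSE],
                               y = age[match(hold, rownames(X))]))
      pr <- predict(b, X[hold, , drop = FALSE])
      evaluate_predictions(pr, age[match(hold, rownames(X))])$r_squared
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(scores)
  out <- cands[[best]]
  attr(out, "cv_r2") <- scores[best]
  attr(out, "trials") <- data.frame(
    trial = seq_len(trials),
    do.call(rbind, lapply(cands, function(h) as.data.frame(h[1:7]))),
    cv_r2 = scores)
  out
}

#' Fit the boosted-tree age clock
#'
#' Trains with the 5,000-round cap and 20-round early-stopping patience
#' against a disjoint holdout; the fitted trees are parsed once for the
#' double-precision attribution engine.
#'
#' @param X training samples-by-proteins matrix (complete, normalized).
#' @param age training ages.
#' @param hyperparams a [clock_hyperparams()].
#' @param eval_X,eval_age holdout evaluation set, disjoint from training.
#' @return a `clock_model`: booster, parsed trees, ordered protein list,
#'   hyperparameters, training ids, best iteration.
#' @export
fit_clock <- function(X, age, hyperparams = clock_hyperparams(),
                      eval_X, eval_age) {
  check_protein_matrix(X, allow_missing = FALSE)
  check_protein_matrix(eval_X, allow_missing = FALSE)
  if (!identical(colnames(X), colnames(eval_X))) {
    fail("train and holdout protein sets differ")
  }
  if (length(intersect(rownames(X), rownames(eval_X)))) {
    fail("holdout overlaps the training set")
  }
  booster <- fit_gbm(X, age, hyperparams,
                     eval = list(X = eval_X, y = eval_age))
  new_clock_model(booster, X, hyperparams)
}

new_clock_model <- function(booster, X, hyperparams) {
  best_iter <- tryCatch(
    suppressWarnings(as.integer(xgboost::xgb.attr(booster, "best_iteration"))),
    error = function(e) NULL)
  if (length(best_iter) != 1 || is.na(best_iter)) best_iter <- NULL
  structure(list(
    booster = booster,
    # best_iteration is 0-based; predict() uses trees 0..best, so must SHAP
    trees = parse_booster(booster, colnames(X),
                          n_trees = if (!is.null(best_iter)) best_iter + 1L),
    proteins = colnames(X),
    hyperparams = hyperparams,
    train_ids = rownames(X),
    best_iter = best_iter
  ), class = "clock_model")
}

#' @export
predict.clock_model <- function(object, newdata, ...) {
  X <- check_model_matrix(object, newdata)
  out <- predict(object$booster, X)
  names(out) <- rownames(X)
  out
}

#' Out-of-fold predicted age for a whole cohort
#'
#' Assigns samples to `k` shuffled folds; each fold's samples are predicted
#' by a model trained on the other folds (with an internal 85:15 split of the
#' training folds providing the early-stopping set, so held-out samples never
#' influence their own model). Every sample is predicted exactly once.
#'
#' @param X complete, normalized samples-by-proteins matrix for the cohort.
#' @param age chronological ages aligned with `X` rows.
#' @param hyperparams a [clock_hyperparams()].
#' @param k folds (>= 2).
#' @param seed seed for fold assignment and inner splits.
#' @param return_models also return the per-fold fitted models (for
#'   consistency checks; memory-heavy on large panels).
#' @return gap table data.frame: sample_id, predicted_age, age, gap
#'   (predicted minus chronological), fold. With `return_models`, a list
#'   `list(gap, models, folds)` instead.
#' @export
oof_predict_age <- function(X, age, hyperparams = clock_hyperparams(), k = 5,
                            seed = 1L, return_models = FALSE) {
  check_protein_matrix(X, allow_missing = FALSE)
  if (k < 2) fail("`k` must be at least 2")
  ids <- rownames(X)
  folds <- make_folds(ids, k, derive_seed(seed, "oof"))
  pred <- setNames(rep(NA_real_, length(ids)), ids)
  fold_id <- setNames(rep(NA_integer_, length(ids)), ids)
  models <- if (return_models) vector("list", length(folds))
  for (f in seq_along(folds)) {
    hold <- folds[[f]]
    tr <- setdiff(ids, hold)
    inner <- split_cohort(tr, train_fraction = 0.85,
                          seed = derive_seed(seed + f, "fit"))
    b <- fit_gbm(X[inner$train, , drop = FALSE],
                 age[match(inner$train, ids)], hyperparams,
                 eval = list(X = X[inner$test, , drop = FALSE],
                             y = age[match(inner$test, ids)]))
    pred[hold] <- predict(b, X[hold, , drop = FALSE])
    fold_id[hold] <- f
    if (return_models) models[[f]] <- new_clock_model(
      X[inner$train, , drop = FALSE], hyperparams = hyperparams, booster = b)
  }
  out <- compute_age_gap(pred, setNames(age, ids))
  out$fold <- fold_id[out$sample_id]
  if (return_models) return(list(gap = out, models = models, folds = folds))
  out
}

#' Proteomic age gap
#'
#' The gap is predicted age minus chronological age, in years; positive
#' values indicate accelerated proteomic aging.
#'
#' @param predicted_age named numeric vector of predicted ages.
#' @param age named numeric vector of chronological ages with the same ids.
#' @return data.frame: sample_id, predicted_age, age, gap.
#' @export
compute_age_gap <- function(predicted_age, age) {
  if (is.null(names(predicted_age)) || is.null(names(age))) {
    if (length(predicted_age) != length(age)) fail("length mismatch")
    ids <- as.character(seq_along(age))
    names(predicted_age) <- names(age) <- ids
  }
  if (!setequal(names(predicted_age), names(age))) {
    fail("sample ids of predicted_age and age do not match")
  }
  ids <- names(predicted_age)
  data.frame(sample_id = ids, predicted_age = as.numeric(predicted_age),
             age = as.numeric(age[ids]),
             gap = as.numeric(predicted_age) - as.numeric(age[ids]),
             stringsAsFactors = FALSE)
}

#' Summarize the age gap by tail bands and deciles
#'
#' Reports the mean gap in the bottom and top `tail_fraction` bands, the mean
#' per decile, and the top-minus-bottom band difference (the headline
#' "years of biological aging" contrast between extreme bands).
#'
#' @param gap_table a gap table from [compute_age_gap()] / [oof_predict_age()].
#' @param tail_fraction band width for the extreme bands (default 5%); must
#'   be below 0.5 so the bands cannot overlap.
#' @return list with `bands` (band, n, mean_gap), `deciles` (decile, n,
#'   mean_gap) and `top_bottom_difference` in years.
#' @export
summarize_gap <- function(gap_table, tail_fraction = 0.05) {
  if (!nrow(gap_table)) fail("empty gap table")
  check_number(tail_fraction, "tail_fraction", lo = 1e-6)
  if (tail_fraction >= 0.5) fail("`tail_fraction` >= 0.5 makes bands overlap")
  g <- gap_table$gap
  lo <- quantile(g, tail_fraction)
  hi <- quantile(g, 1 - tail_fraction)
  bands <- data.frame(
    band = c(sprintf("bottom_%g%%", 100 * tail_fraction),
             sprintf("top_%g%%", 100 * tail_fraction)),
    n = c(sum(g <= lo), sum(g >= hi)),
    mean_gap = c(mean(g[g <= lo]), mean(g[g >= hi])))
  dec <- cut(g, quantile(g, 0:10 / 10), include.lowest = TRUE,
             labels = FALSE)
  deciles <- data.frame(
    decile = 1:10,
    n = as.integer(table(factor(dec, levels = 1:10))),
    mean_gap = as.numeric(tapply(g, factor(dec, levels = 1:10), mean)))
  list(bands = bands, deciles = deciles,
       top_bottom_difference = bands$mean_gap[2] - bands$mean_gap[1])
}

#' Prediction accuracy metrics
#'
#' Pearson r, coefficient of determination R-squared (1 - SS_res / SS_tot),
#' RMSE and MAE.
#'
#' @param pred predicted values.
#' @param actual observed values (length >= 2).
#' @return list: pearson_r, r_squared, rmse, mae.
#' @export
evaluate_predictions <- function(pred, actual) {
  if (length(pred) != length(actual)) fail("length mismatch")
  if (length(actual) < 2) fail("need at least 2 observations")
  res <- pred - actual
  sst <- sum((actual - mean(actual))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(res^2) / sst
  list(pearson_r = safe_cor(pred, actual), r_squared = r2,
       rmse = sqrt(mean(res^2)), mae = mean(abs(res)))
}

# penalty grid matching the published tuning space (scikit-learn "alpha";
# glmnet's lambda plays the same role up to its 1/n scaling convention)
.lasso_lambda_grid <- c(1e-15, 1e-10, 1e-8, 1e-5, 1e-4, 1e-3, 1e-2,
                        1, 5, 10, 50, 100)
.enet_l1_ratios <- c(0.1, 0.5, 0.7, 0.9, 0.95, 0.99, 1)

#' Benchmark the boosted clock against penalized linear baselines
#'
#' Fits the boosted-tree clock, a cross-validated LASSO and a cross-validated
#' elastic net (penalty grid 1e-15..100; elastic-net mixing over
#' 0.1..1) on the training set and evaluates all of them on each evaluation
#' set.
#'
#' @param train_X,train_age training data (complete).
#' @param eval_sets named list of evaluation sets, each
#'   `list(X = matrix, age = numeric)` sharing the training proteins.
#' @param hyperparams boosted-tree settings.
#' @param seed seed for the internal early-stopping split and CV folds.
#' @return data.frame: model, eval_set, pearson_r, r_squared, rmse, mae.
#' @export
benchmark_baselines <- function(train_X, train_age, eval_sets,
                                hyperparams = clock_hyperparams(),
                                seed = 1L) {
  check_protein_matrix(train_X, allow_missing = FALSE)
  for (es in eval_sets) {
    check_protein_matrix(es$X, allow_missing = FALSE)
    if (!identical(colnames(es$X), colnames(train_X))) {
      fail("evaluation sets must share the training protein set")
    }
  }
  inner <- split_cohort(rownames(train_X), 0.85, derive_seed(seed, "fit"))
  idx <- match(inner$train, rownames(train_X))
  gbm <- fit_gbm(train_X[idx, , drop = FALSE], train_age[idx], hyperparams,
                 eval = list(X = train_X[-idx, , drop = FALSE],
                             y = train_age[-idx]))
  set.seed(derive_seed(seed, "tune"))
  lasso <- glmnet::cv.glmnet(train_X, train_age, alpha = 1,
                             lambda = sort(.lasso_lambda_grid, TRUE))
  enet_fits <- lapply(.enet_l1_ratios, function(a) {
    set.seed(derive_seed(seed, "tune"))
    glmnet::cv.glmnet(train_X, train_age, alpha = a,
                      lambda = sort(.lasso_lambda_grid, TRUE))
  })
  enet_best <- which.min(vapply(enet_fits, function(f) min(f$cvm), numeric(1)))
  enet <- enet_fits[[enet_best]]

  predictors <- list(
    gbm = function(X) predict(gbm, X),
    lasso = function(X) as.numeric(predict(lasso, X, s = "lambda.min")),
    elastic_net = function(X) as.numeric(predict(enet, X, s = "lambda.min")))
  out <- do.call(rbind, lapply(names(predictors), function(mn) {
    do.call(rbind, lapply(names(eval_sets), function(en) {
      m <- evaluate_predictions(predictors[[mn]](eval_sets[[en]]$X),
                                eval_sets[[en]]$age)
      data.frame(model = mn, eval_set = en, pearson_r = m$pearson_r,
                 r_squared = m$r_squared, rmse = m$rmse, mae = m$mae,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Save / load a fitted clock model
#'
#' Writes the booster in xgboost's portable JSON format next to a metadata
#' JSON (protein order, hyperparameters) and a plain-text protein list.
#'
#' @param model a `clock_model`.
#' @param path directory to write into (created if needed).
#' @export
save_clock_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(path, "booster.json"))
  writeLines(model$proteins, file.path(path, "proteins.txt"))
  jsonlite::write_json(
    list(version = 1L, proteins = model$proteins,
         hyperparams = unclass(model$hyperparams)),
    file.path(path, "model_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_clock_model
#' @export
load_clock_model <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "model_meta.json"),
                              simplifyVector = TRUE)
  booster <- xgboost::xgb.load(file.path(path, "booster.json"))
  hp <- do.call(clock_hyperparams, as.list(meta$hyperparams))
  X0 <- matrix(numeric(0), 0, length(meta$proteins),
               dimnames = list(NULL, meta$proteins))
  new_clock_model(booster, X0, hp)
}
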