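# one shadow copy per column: an independent permutation of its values.
# A minimum shadow-pool size is enforced (classic Boruta uses >= 5): with
# very few surviving features the max over their shadows alone is a weak
# null and chance survivors would sail through late iterations.
make_shadows <- function(X, seed, min_shadows = 1) {
  set.seed(seed)
  shadows <- apply(X, 2, sample)
  colnames(shadows) <- paste0(".shadow.", colnames(X))
  rownames(shadows) <- rownames(X)
  extra <- 0L
  while (ncol(shadows) < min_shadows) {
    extra <- extra + 1L
    j <- (extra - 1L) %% ncol(X) + 1L
    more <- sample(X[, j])
    shadows <- cbind(shadows, more)
    colnames(shadows)[ncol(shadows)] <-
      paste0(".shadow", extra, ".", colnames(X)[j])
  }
  shadows
}

# removal rule: unanimous fold argmin wins; otherwise the protein ranked
# lowest in the greatest number of folds; residual ties lexicographic
vote_removal <- function(fold_argmins) {
  votes <- table(fold_argmins)
  top <- names(votes)[votes == max(votes)]
  sort(top)[1]
}

# mean |Shapley| importance for a raw booster on its training columns
booster_importance <- function(booster, X, n_trees = NULL) {
  trees <- parse_booster(booster, colnames(X), n_trees = n_trees)
  phi <- cpp_tree_shap(trees, X, trees$base_score)
  setNames(colMeans(abs(phi[, seq_len(ncol(X)), drop = FALSE])), colnames(X))
}

#' Boruta shadow-feature selection with Shapley importance
#'
#' Iterative Boruta: in each iteration, every surviving protein is paired
#' with a shadow copy (an independent permutation of its column, i.e. pure
#' noise with the same marginal distribution); the shadow pool is padded to
#' at least five columns so late iterations with few survivors still face a
#' meaningful importance null. Per trial a boosted model is
#' fitted on real plus shadow features and each feature's mean absolute
#' Shapley attribution is computed; importances and the shadow reference (at
#' `threshold = 1` the maximum shadow importance, otherwise that quantile of
#' the shadow importances) are averaged across trials. Proteins whose
#' averaged importance fails to exceed the averaged shadow reference are
#' dropped, and iterations repeat until no protein fails.
#'
#' @param X complete samples-by-proteins matrix.
#' @param y outcome (chronological age).
#' @param hyperparams boosted-tree settings for the selection fits.
#' @param trials models fitted per iteration (importances averaged over
#'   trials).
#' @param threshold fraction of shadow features a protein must beat (1 =
#'   all of them).
#' @param seed RNG seed; shadow permutations are re-drawn every trial.
#' @param nrounds optional fixed boosting-round count per selection fit. The
#'   default (`NULL`) trains each trial with the hyperparameters' estimator
#'   cap and early stopping against an internal 85:15 holdout, which is what
#'   keeps the false-positive rate down on signal-free data: with nothing to
#'   predict, early stopping halts almost immediately and no feature can
#'   accumulate importance over its shadows.
#' @return list of class `boruta_result`: `selected`, `dropped` (list of
#'   per-iteration drops), `history` (data.frame of per-iteration mean
#'   importances and the shadow reference), `trials`, `threshold`.
#' @export
boruta_select <- function(X, y, hyperparams = clock_hyperparams(),
                          trials = 200, threshold = 1.0, seed = 1L,
                          nrounds = NULL) {
  check_protein_matrix(X, allow_missing = FALSE)
  if (trials < 1) fail("`trials` must be at least 1")
  check_number(threshold, "threshold", lo = 0, hi = 1)
  surviving <- colnames(X)
  dropped <- list()
  history <- list()
  iter <- 0L
  base_seed <- derive_seed(seed, "boruta")
  while (length(surviving) > 0) {
    iter <- iter + 1L
    imp_sum <- setNames(numeric(length(surviving)), surviving)
    shadow_ref_sum <- 0
    for (t in seq_len(trials)) {
      shadows <- make_shadows(X[, surviving, drop = FALSE],
                              (base_seed + iter * 100003 + t) %% 2147483647,
                              min_shadows = 5)
      Xa <- cbind(X[, surviving, drop = FALSE], shadows)
      hp <- hyperparams
      hp$seed <- as.integer((base_seed + iter * 100003 + t) %% 2147483647)
      if (is.null(nrounds)) {
        inner <- split_cohort(rownames(Xa), 0.85, hp$seed)
        booster <- fit_gbm(Xa[inner$train, , drop = FALSE],
                           y[match(inner$train, rownames(Xa))], hp,
                           eval = list(X = Xa[inner$test, , drop = FALSE],
                                       y = y[match(inner$test, rownames(Xa))]))
        n_keep <- as.integer(xgboost::xgb.attr(booster, "best_iteration")) + 1L
        imp <- booster_importance(booster, Xa[inner$train, , drop = FALSE],
                                  n_trees = n_keep)
      } else {
        booster <- fit_gbm(Xa, y, hp, nrounds = nrounds)
        imp <- booster_importance(booster, Xa)
      }
      real <- imp[surviving]
      shadow <- imp[colnames(shadows)]
      imp_sum <- imp_sum + real
      shadow_ref_sum <- shadow_ref_sum +
        as.numeric(quantile(shadow, threshold, type = 7))
    }
    mean_imp <- imp_sum / trials
    shadow_ref <- shadow_ref_sum / trials
    failing <- surviving[mean_imp <= shadow_ref]
    history[[iter]] <- data.frame(
      iteration = iter, protein = surviving,
      importance = as.numeric(mean_imp), shadow_reference = shadow_ref,
      dropped = surviving %in% failing, stringsAsFactors = FALSE)
    if (!length(failing)) break
    dropped[[iter]] <- failing
    surviving <- setdiff(surviving, failing)
  }
  if (!length(surviving)) {
    warning("Boruta dropped every feature", call. = FALSE)
  }
  structure(list(selected = surviving, dropped = dropped,
                 history = do.call(rbind, history), trials = trials,
                 threshold = threshold, seed = seed),
            class = "boruta_result")
}

#' SHAP-guided recursive feature elimination
#'
#' Starting from a selected panel, repeatedly fits `k`-fold cross-validated
#' boosted models, records mean CV Pearson r and R-squared for the current
#' panel, and removes one protein per step until five remain. The protein
#' removed is the per-fold least-important one when all folds agree;
#' otherwise the protein ranked lowest in the greatest number of folds, with
#' residual ties broken lexicographically by protein id.
#'
#' @param X complete samples-by-proteins matrix (training data).
#' @param y outcome (chronological age).
#' @param selected character vector of panel proteins (>= 6).
#' @param hyperparams boosted-tree settings.
#' @param k CV folds.
#' @param seed fold-assignment seed.
#' @param nrounds boosting rounds per CV fit.
#' @return object of class `rfe_curve`: `curve` (data.frame: size,
#'   pearson_r, r_squared, removed), `selected` (the starting panel),
#'   `elimination` (proteins in removal order).
#' @export
shap_rfe <- function(X, y, selected, hyperparams = clock_hyperparams(),
                     k = 5, seed = 1L, nrounds = 100) {
  check_protein_matrix(X, allow_missing = FALSE)
  if (k < 2) fail("`k` must be at least 2")
  if (length(selected) < 6) fail("need at least 6 selected proteins")
  if (!all(selected %in% colnames(X))) fail("selected proteins absent from X")
  ids <- rownames(X)
  folds <- make_folds(ids, k, derive_seed(seed, "rfe"))
  panel <- selected
  rows <- list()
  elim <- character(0)
  step <- 0L
  while (TRUE) {
    step <- step + 1L
    fold_r <- fold_r2 <- numeric(k)
    fold_imp <- matrix(0, k, length(panel),
                       dimnames = list(NULL, panel))
    for (f in seq_len(k)) {
      hold <- folds[[f]]
      tr <- setdiff(ids, hold)
      hp <- hyperparams
      hp$seed <- as.integer(derive_seed(seed + f, "rfe"))
      b <- fit_gbm(X[tr, panel, drop = FALSE], y[match(tr, ids)], hp,
                   nrounds = nrounds)
      pr <- predict(b, X[hold, panel, drop = FALSE])
      m <- evaluate_predictions(pr, y[match(hold, ids)])
      fold_r[f] <- m$pearson_r
      fold_r2[f] <- m$r_squared
      fold_imp[f, ] <- booster_importance(b, X[tr, panel, drop = FALSE])
    }
    removed <- NA_character_
    if (length(panel) > 5) {
      removed <- vote_removal(apply(fold_imp, 1,
                                    function(v) panel[which.min(v)]))
    }
    rows[[step]] <- data.frame(size = length(panel),
                               pearson_r = mean(fold_r),
                               r_squared = mean(fold_r2),
                               removed = removed, stringsAsFactors = FALSE)
    if (length(panel) <= 5) break
    elim <- c(elim, removed)
    panel <- setdiff(panel, removed)
  }
  structure(list(curve = do.call(rbind, rows), selected = selected,
                 elimination = elim),
            class = "rfe_curve")
}

#' Pick the smallest panel retaining a fraction of full-panel performance
#'
#' Scans the elimination curve for the smallest panel whose metric is at
#' least `retain` times the full panel's metric, and returns that panel's
#' protein set (reconstructed from the removal order).
#'
#' @param rfe an [shap_rfe()] result.
#' @param retain retained-performance fraction in (0, 1\].
#' @param metric `"pearson_r"` or `"r_squared"`.
#' @return character vector of panel proteins.
#' @export
select_reduced_panel <- function(rfe, retain = 0.95, metric = "pearson_r") {
  if (!inherits(rfe, "rfe_curve")) fail("`rfe` must be an rfe_curve")
  if (!is.finite(retain) || retain <= 0 || retain > 1) {
    fail("`retain` must be in (0, 1]")
  }
  metric <- match.arg(metric, c("pearson_r", "r_squared"))
  curve <- rfe$curve
  full <- curve[[metric]][1]
  ok <- curve$size[curve[[metric]] >= retain * full]
  size <- if (length(ok)) min(ok) else curve$size[1]
  panel_at_size(rfe, size)
}

panel_at_size <- function(rfe, size) {
  n_removed <- length(rfe$selected) - size
  if (n_removed < 0 || n_removed > length(rfe$elimination)) {
    fail("requested panel size not on the curve")
  }
  setdiff(rfe$selected, head(rfe$elimination, n_removed))
}
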