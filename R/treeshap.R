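#' @useDynLib protclock, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Parse a fitted booster into flat tree arrays
#'
#' Converts an xgboost booster's text dump into the flat node arrays consumed
#' by the double-precision TreeSHAP engine. Node "cover" (the training-sample
#' weight reaching each node) supplies the weights used for conditional
#' expectations when a feature is absent from a coalition.
#'
#' @param booster an `xgb.Booster`.
#' @param feature_names character vector of feature names in training column
#'   order; split features in the dump are matched against it.
#' @param n_trees optional cap on the number of trees kept (used to honour
#'   early stopping: the booster's own `predict` only uses trees up to the
#'   best iteration).
#' @return list of flat arrays (`left`, `right`, `missing`, `feature`,
#'   `threshold`, `value`, `cover`, per-tree `offset`/`n_nodes`/`max_depth`)
#'   plus the booster's `base_score`.
#' @keywords internal
parse_booster <- function(booster, feature_names, n_trees = NULL) {
  dt <- xgboost::xgb.model.dt.tree(model = booster)
  dt <- dt[order(dt$Tree, dt$Node), ]
  if (!is.null(n_trees)) dt <- dt[dt$Tree < n_trees, ]
  node_of <- function(id) as.integer(sub(".*-", "", id))
  is_leaf <- dt$Feature == "Leaf"
  feat <- match(dt$Feature, feature_names) - 1L
  if (any(!is_leaf & is.na(feat))) {
    stop("booster splits on features absent from `feature_names`")
  }
  feat[is_leaf] <- -1L
  left <- ifelse(is_leaf, -1L, node_of(dt$Yes))
  right <- ifelse(is_leaf, -1L, node_of(dt$No))
  missing <- ifelse(is_leaf, -1L, node_of(dt$Missing))
  value <- ifelse(is_leaf, dt$Gain, 0)
  threshold <- ifelse(is_leaf, NA_real_, dt$Split)

  trees <- sort(unique(dt$Tree))
  n_nodes <- as.integer(table(factor(dt$Tree, levels = trees)))
  offset <- c(0L, cumsum(n_nodes)[-length(n_nodes)])

  depth_of_tree <- function(l, r) {
    d <- integer(length(l))
    # nodes are stored parent-before-child in xgboost dumps
    for (k in seq_along(l)) {
      if (l[k] >= 0) {
        d[l[k] + 1L] <- d[k] + 1L
        d[r[k] + 1L] <- d[k] + 1L
      }
    }
    max(d)
  }
  max_depth <- vapply(seq_along(trees), function(t) {
    idx <- offset[t] + seq_len(n_nodes[t])
    depth_of_tree(left[idx], right[idx])
  }, integer(1))

  cfg <- xgboost::xgb.config(booster)
  base_score <- as.numeric(cfg$learner$learner_model_param$base_score)

  list(
    left = as.integer(left), right = as.integer(right),
    missing = as.integer(missing), feature = as.integer(feat),
    threshold = as.numeric(threshold), value = as.numeric(value),
    cover = as.numeric(dt$Cover),
    offset = offset, n_nodes = n_nodes, max_depth = as.integer(max_depth),
    base_score = base_score
  )
}

#' Per-sample Shapley attributions for a fitted clock
#'
#' Computes exact path-dependent tree Shapley values in double precision.
#' The returned matrix has one column per protein plus a final `"(bias)"`
#' column holding the model's expected value, so each row sums to the model
#' prediction for that sample (local additivity).
#'
#' @param model a [fit_clock()] model.
#' @param data numeric samples-by-proteins matrix containing exactly the
#'   model's proteins (any column order; matched by name).
#' @return numeric matrix, `nrow(data)` x `(n_proteins + 1)`.
#' @export
shap_values <- function(model, data) {
  X <- check_model_matrix(model, data)
  phi <- cpp_tree_shap(model$trees, X, model$trees$base_score)
  colnames(phi) <- c(model$proteins, "(bias)")
  rownames(phi) <- rownames(X)
  phi
}

#' Mean absolute Shapley importance per protein
#'
#' The per-protein mean of absolute Shapley attributions across a sample set:
#' the importance score that drives both shadow-feature selection and
#' SHAP-guided recursive elimination.
#'
#' @inheritParams shap_values
#' @return named non-negative numeric vector, one entry per model protein.
#' @export
shap_importance <- function(model, data) {
  phi <- shap_values(model, data)
  imp <- colMeans(abs(phi[, seq_along(model$proteins), drop = FALSE]))
  names(imp) <- model$proteins
  imp
}

#' Double-precision model evaluation from the parsed trees
#'
#' Evaluates the parsed ensemble exactly; used to verify local additivity of
#' attributions and agreement with the booster's own predictions.
#'
#' @inheritParams shap_values
#' @return numeric vector of predictions.
#' @export
predict_exact <- function(model, data) {
  X <- check_model_matrix(model, data)
  out <- cpp_predict_trees(model$trees, X, model$trees$base_score)
  names(out) <- rownames(X)
  out
}
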