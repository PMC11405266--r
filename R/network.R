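#' Shapley interaction matrix for a fitted clock
#'
#' Computes exact pairwise tree Shapley interaction values per sample and
#' aggregates them as the mean absolute value across samples. The diagonal
#' holds main-effect attributions; off-diagonal entries quantify how much a
#' protein pair contributes jointly beyond their separate effects. Per-sample
#' signed interaction rows sum to the per-feature attribution vector (the
#' additivity identity asserted in tests), so set `per_sample = TRUE` only
#' for small inputs (memory is O(n p^2)).
#'
#' @param model a `clock_model`.
#' @param data complete samples-by-proteins matrix with the model proteins.
#' @param per_sample also return the full per-sample interaction array.
#' @return list of class `interaction_matrix`: `mean_abs` (p x p symmetric
#'   matrix over proteins), and when requested `per_sample`
#'   (n x (p+1) x (p+1), last index the bias) plus `phi` (the per-sample
#'   attributions).
#' @export
shap_interaction_matrix <- function(model, data, per_sample = FALSE) {
  X <- check_model_matrix(model, data)
  if (length(model$trees$offset) == 0) {
    warning("model has no trees; interactions all zero", call. = FALSE)
  }
  res <- cpp_tree_shap_interactions(model$trees, X, model$trees$base_score,
                                    per_sample)
  p <- length(model$proteins)
  mean_abs <- res$mean_abs[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(mean_abs) <- list(model$proteins, model$proteins)
  out <- list(mean_abs = mean_abs, proteins = model$proteins)
  if (per_sample) {
    out$per_sample <- res$per_sample
    dimnames(out$per_sample) <- list(rownames(X),
                                     c(model$proteins, "(bias)"),
                                     c(model$proteins, "(bias)"))
    out$phi <- shap_values(model, data)
  }
  structure(out, class = "interaction_matrix")
}

#' Threshold an interaction matrix into a protein network
#'
#' Keeps undirected edges whose mean absolute interaction is at least the
#' threshold. Instead of a fixed threshold (the published network used
#' 0.0083 on its own cohort), `target_nodes` picks the smallest threshold
#' whose network has at most that many connected nodes, to size-match a
#' reference subnetwork.
#'
#' @param imat an [shap_interaction_matrix()] result (or a symmetric matrix).
#' @param threshold minimum edge weight (>= 0).
#' @param target_nodes alternative to `threshold`: auto-choose it so the
#'   number of connected nodes is as close as possible to (and at most)
#'   `target_nodes`.
#' @return `protein_network`: `edges` (data.frame a, b, weight), `nodes`,
#'   `degree` (named vector over connected nodes), `threshold`.
#' @export
build_interaction_network <- function(imat, threshold = NULL,
                                      target_nodes = NULL) {
  M <- if (inherits(imat, "interaction_matrix")) imat$mean_abs else imat
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-8))) {
    fail("interaction matrix must be symmetric")
  }
  if (is.null(threshold) && is.null(target_nodes)) {
    fail("supply `threshold` or `target_nodes`")
  }
  ut <- upper.tri(M)
  weights <- M[ut]
  if (!is.null(target_nodes)) {
    cand <- sort(unique(weights), decreasing = TRUE)
    threshold <- Inf
    for (th in cand) {
      keep <- which(M >= th & ut, arr.ind = TRUE)
      n_nodes <- length(unique(c(keep)))
      if (n_nodes > target_nodes) break
      threshold <- th
    }
  }
  if (threshold < 0) fail("`threshold` must be >= 0")
  keep <- which(M >= threshold & ut, arr.ind = TRUE)
  edges <- data.frame(a = rownames(M)[keep[, 1]], b = colnames(M)[keep[, 2]],
                      weight = M[keep], stringsAsFactors = FALSE)
  protein_network(edges, threshold)
}

protein_network <- function(edges, threshold = 0) {
  nodes <- sort(unique(c(edges$a, edges$b)))
  degree <- setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(c(edges$a, edges$b))
    degree[names(tab)] <- as.integer(tab)
  }
  structure(list(edges = edges, nodes = nodes, degree = degree,
                 threshold = threshold),
            class = "protein_network")
}

#' Filter a reference edge list into a high-confidence network
#'
#' Keeps edges whose confidence is strictly above `min_confidence` (the
#' published networks used coexpression evidence at confidence > 0.7), then
#' iteratively prunes nodes of degree below `min_degree` until a fixed point
#' is reached.
#'
#' @param edges data.frame with columns `a`, `b`, `score` (confidence in
#'   \[0, 1\]); malformed rows (missing ids or scores) are skipped with a
#'   warning naming the row.
#' @param min_confidence strict lower bound on edge confidence.
#' @param min_degree minimum node degree retained.
#' @return a `protein_network`.
#' @export
filter_reference_edges <- function(edges, min_confidence = 0.7,
                                   min_degree = 2) {
  if (!nrow(edges)) return(protein_network(edges[0, ], min_confidence))
  bad <- which(is.na(edges$a) | is.na(edges$b) | !is.finite(edges$score) |
                 edges$a == "" | edges$b == "")
  if (length(bad)) {
    warning("skipping malformed edge rows: ",
            paste(head(bad, 10), collapse = ", "), call. = FALSE)
    edges <- edges[-bad, , drop = FALSE]
  }
  if (any(edges$score < 0 | edges$score > 1)) {
    fail("confidence scores must lie in [0, 1]")
  }
  edges <- edges[edges$score > min_confidence, , drop = FALSE]
  # de-duplicate unordered pairs, keeping the highest score
  key <- ifelse(edges$a < edges$b, paste(edges$a, edges$b),
                paste(edges$b, edges$a))
  edges <- edges[order(key, -edges$score), , drop = FALSE]
  edges <- edges[!duplicated(ifelse(edges$a < edges$b,
                                    paste(edges$a, edges$b),
                                    paste(edges$b, edges$a))), , drop = FALSE]
  repeat {
    deg <- table(c(edges$a, edges$b))
    drop_nodes <- names(deg)[deg < min_degree]
    if (!length(drop_nodes) || !nrow(edges)) break
    edges <- edges[!(edges$a %in% drop_nodes | edges$b %in% drop_nodes), ,
                   drop = FALSE]
  }
  out <- edges[, c("a", "b", "score")]
  names(out)[3] <- "weight"
  protein_network(out, min_confidence)
}

#' Overlap statistics between two protein networks
#'
#' Jaccard overlap of node sets and of unordered edge sets.
#'
#' @param net1,net2 `protein_network` objects.
#' @return list: shared_nodes, node_jaccard, shared_edges, edge_jaccard.
#' @export
network_overlap <- function(net1, net2) {
  ekey <- function(net) {
    if (!nrow(net$edges)) return(character(0))
    ifelse(net$edges$a < net$edges$b,
           paste(net$edges$a, net$edges$b),
           paste(net$edges$b, net$edges$a))
  }
  n_int <- length(intersect(net1$nodes, net2$nodes))
  n_un <- length(union(net1$nodes, net2$nodes))
  e1 <- ekey(net1); e2 <- ekey(net2)
  e_int <- length(intersect(e1, e2))
  e_un <- length(union(e1, e2))
  list(shared_nodes = n_int,
       node_jaccard = if (n_un) n_int / n_un else NA_real_,
       shared_edges = e_int,
       edge_jaccard = if (e_un) e_int / e_un else NA_real_)
}
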