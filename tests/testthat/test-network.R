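interacting_model <- function(n = 250, seed = 1) {
  set.seed(seed)
  X <- named_matrix(rnorm(n * 5), n, 5)
  y <- 2 * X[, 1] * X[, 2] + X[, 3] + rnorm(n, 0, 0.1)
  list(model = fit_small_model(X, y, nrounds = 40, max_depth = 3), X = X)
}

test_that("the interaction matrix is symmetric, named and detects planted pairs", {
  d <- interacting_model()
  im <- shap_interaction_matrix(d$model, d$X)
  M <- im$mean_abs
  expect_equal(dim(M), c(5, 5))
  expect_equal(rownames(M), colnames(d$X))
  expect_equal(M, t(M))
  off <- M; diag(off) <- 0
  expect_equal(which(off == max(off), arr.ind = TRUE)[1, ],
               c(row = 2L, col = 1L), ignore_attr = TRUE)
})

test_that("per-sample interaction rows reconstruct the attributions", {
  d <- interacting_model(n = 60, seed = 2)
  im <- shap_interaction_matrix(d$model, d$X[1:20, ], per_sample = TRUE)
  ps <- im$per_sample
  expect_equal(dim(ps), c(20, 6, 6))
  for (i in 1:20) {
    expect_equal(ps[i, , ], t(ps[i, , ]), tolerance = 1e-10)
    expect_equal(unname(rowSums(ps[i, , ])), unname(im$phi[i, ]),
                 tolerance = 1e-8)
  }
})

test_that("thresholding builds exactly the edges at or above the cut", {
  M <- matrix(0, 4, 4, dimnames = list(paste0("P", 1:4), paste0("P", 1:4)))
  M["P1", "P2"] <- M["P2", "P1"] <- 0.5
  M["P2", "P3"] <- M["P3", "P2"] <- 0.3
  M["P3", "P4"] <- M["P4", "P3"] <- 0.1
  net <- build_interaction_network(M, threshold = 0.3)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$nodes, c("P1", "P2", "P3"))
  expect_equal(unname(net$degree["P2"]), 2L)
  expect_error(build_interaction_network(M), "threshold")
  A <- M; A["P1", "P2"] <- 9
  expect_error(build_interaction_network(A, threshold = 0.1), "symmetric")
})

test_that("target_nodes picks the loosest threshold not exceeding the size", {
  M <- matrix(0, 5, 5, dimnames = list(paste0("P", 1:5), paste0("P", 1:5)))
  w <- c(0.9, 0.7, 0.5, 0.2)
  M["P1", "P2"] <- M["P2", "P1"] <- w[1]
  M["P2", "P3"] <- M["P3", "P2"] <- w[2]
  M["P3", "P4"] <- M["P4", "P3"] <- w[3]
  M["P4", "P5"] <- M["P5", "P4"] <- w[4]
  net3 <- build_interaction_network(M, target_nodes = 3)
  expect_setequal(net3$nodes, c("P1", "P2", "P3"))
  expect_equal(net3$threshold, 0.7)
  net4 <- build_interaction_network(M, target_nodes = 4)
  expect_setequal(net4$nodes, paste0("P", 1:4))
  # target larger than any achievable network keeps everything
  expect_setequal(build_interaction_network(M, target_nodes = 10)$nodes,
                  paste0("P", 1:5))
})

test_that("reference filtering is strictly above the cut and prunes to degree two", {
  edges <- data.frame(
    a = c("A", "B", "C", "A", "D", "E"),
    b = c("B", "C", "A", "D", "E", "F"),
    score = c(0.9, 0.8, 0.75, 0.7, 0.9, 0.95),
    stringsAsFactors = FALSE)
  net <- filter_reference_edges(edges, min_confidence = 0.7, min_degree = 2)
  # A-D at exactly 0.7 is excluded (strict); D-E, E-F then die by degree
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$degree >= 2))
})

test_that("degree pruning iterates to a fixed point", {
  # a chain: every interior node starts at degree 2 but pruning the ends
  # cascades until nothing is left
  edges <- data.frame(a = c("A", "B", "C", "D"),
                      b = c("B", "C", "D", "E"),
                      score = rep(0.9, 4), stringsAsFactors = FALSE)
  net <- filter_reference_edges(edges, min_degree = 2)
  expect_equal(nrow(net$edges), 0)
  expect_length(net$nodes, 0)
})

test_that("malformed rows are skipped with a warning and duplicates keep the best score", {
  edges <- data.frame(a = c("A", "", "B", "A"),
                      b = c("B", "C", "A", "B"),
                      score = c(0.8, 0.9, 0.95, NA),
                      stringsAsFactors = FALSE)
  expect_warning(net <- filter_reference_edges(edges, min_degree = 1),
                 "malformed")
  expect_equal(nrow(net$edges), 1)   # A-B and B-A collapse to one
  expect_equal(net$edges$weight, 0.95)
  expect_error(filter_reference_edges(
    data.frame(a = "A", b = "B", score = 1.4)), "\\[0, 1\\]")
})

test_that("network overlap reports Jaccard statistics", {
  n1 <- protclock:::protein_network(
    data.frame(a = c("A", "B"), b = c("B", "C"), weight = 1))
  n2 <- protclock:::protein_network(
    data.frame(a = c("B", "C"), b = c("A", "D"), weight = 1))
  ov <- network_overlap(n1, n2)
  expect_equal(ov$shared_nodes, 3)
  expect_equal(ov$node_jaccard, 3 / 4)
  expect_equal(ov$shared_edges, 1)   # A-B matches B-A (unordered)
  expect_equal(ov$edge_jaccard, 1 / 3)
})
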