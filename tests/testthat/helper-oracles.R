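# Shared fixtures and independent oracles used across the suite.

# round-trip a double through IEEE single precision (the booster's internal
# representation for split decisions)
f32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4), "numeric",
          n = length(x), size = 4)
}

# conditional expectation of the parsed ensemble given a feature subset S
# (1-based indices): splits on features in S follow x, others average the
# children weighted by cover. This is the enumeration oracle's value game.
expvalue_trees <- function(trees, x, S) {
  tot <- trees$base_score
  for (t in seq_along(trees$offset)) {
    off <- trees$offset[t]
    rec <- function(node) {
      i <- off + node + 1
      if (trees$left[i] < 0) return(trees$value[i])
      f <- trees$feature[i] + 1
      if (f %in% S) {
        if (f32(x[f]) < f32(trees$threshold[i])) rec(trees$left[i])
        else rec(trees$right[i])
      } else {
        li <- off + trees$left[i] + 1
        ri <- off + trees$right[i] + 1
        (trees$cover[li] * rec(trees$left[i]) +
           trees$cover[ri] * rec(trees$right[i])) / trees$cover[i]
      }
    }
    tot <- tot + rec(0)
  }
  tot
}

# brute-force Shapley values by enumeration over feature subsets
brute_shap <- function(trees, x, p) {
  vapply(seq_len(p), function(i) {
    others <- setdiff(seq_len(p), i)
    tot <- 0
    for (k in 0:length(others)) {
      combs <- if (k == 0) list(integer(0)) else
        asplit(utils::combn(others, k), 2)
      for (S in combs) {
        w <- factorial(k) * factorial(p - k - 1) / factorial(p)
        tot <- tot + w * (expvalue_trees(trees, x, c(S, i)) -
                            expvalue_trees(trees, x, S))
      }
    }
    tot
  }, numeric(1))
}

# step-up BH directly from its definition: q_(i) = min_{j >= i} m p_(j) / j
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# hand product-limit estimator: cumulative incidence at each distinct event
# time, 1 - prod(1 - d_j / n_j)
hand_km <- function(time, event) {
  ut <- sort(unique(time[event]))
  surv <- 1
  out <- data.frame(time = ut, incidence = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event)
    surv <- surv * (1 - d / at_risk)
    out$incidence[i] <- 1 - surv
  }
  out
}

# minimal covariate/phenotype table for survival and association fits
make_cov_table <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    age = runif(n, 39, 71), sex = rbinom(n, 1, 0.5),
    deprivation = rnorm(n),
    center = factor(sample(c("A", "B", "C"), n, TRUE)),
    activity = factor(sample(c("low", "mod", "high"), n, TRUE)),
    smoking = factor(sample(c("never", "prev", "cur"), n, TRUE)),
    bmi = rnorm(n, 27, 4.8), hypertension = rbinom(n, 1, 0.3),
    stringsAsFactors = FALSE)
}

# small fitted boosted model on a named matrix (no early stopping)
fit_small_model <- function(X, y, nrounds = 5, eta = 0.3, max_depth = 3,
                            subsample = 1, colsample = 1, seed = 1) {
  hp <- clock_hyperparams(eta = eta, max_depth = max_depth,
                          subsample = subsample,
                          colsample_bytree = colsample, seed = seed)
  b <- protclock:::fit_gbm(X, y, hp, nrounds = nrounds)
  protclock:::new_clock_model(b, X, hp)
}

named_matrix <- function(data, n, p, prefix = "P") {
  matrix(data, n, p, dimnames = list(sprintf("S%05d", seq_len(n)),
                                     paste0(prefix, seq_len(p))))
}
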