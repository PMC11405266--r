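test_that("BH adjustment matches the step-up definition and rejects bad input", {
  set.seed(1)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), p.adjust(c(0.01, 0.02, 0.03), "BH"))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("adjustment tiers nest as documented", {
  t1 <- protclock:::tier_covariates(1)
  t2 <- protclock:::tier_covariates(2)
  t3 <- protclock:::tier_covariates(3)
  expect_equal(t1, c("age", "sex"))
  expect_true(all(t1 %in% t2) && all(t2 %in% t3))
  expect_setequal(setdiff(t3, t2), c("bmi", "hypertension"))
  expect_error(protclock:::tier_covariates(4), "tier")
})

test_that("association scan recovers a planted linear effect and flags binaries", {
  n <- 800
  ph <- make_cov_table(n, seed = 2)
  set.seed(3)
  gap <- rnorm(n, 0, 3)
  gt <- data.frame(sample_id = ph$sample_id, gap = gap)
  ph$marker <- 0.4 * gap + 0.1 * ph$age + rnorm(n, 0, 1)
  ph$flag <- rbinom(n, 1, plogis(0.3 * gap))
  ph$null_ph <- rnorm(n)
  out <- association_scan(gt, ph, c("marker", "flag", "null_ph"))
  expect_equal(out$family, c("linear", "logistic", "linear"))
  expect_equal(out$beta[1], 0.4, tolerance = 0.05)
  expect_equal(out$beta[2], 0.3, tolerance = 0.1)
  expect_lt(out$q[1], 0.01)
  expect_gt(out$p[3], 0.001)
  expect_equal(out$q, bh_fdr(out$p))
})

test_that("association scan honours subsets and skips single-class phenotypes", {
  n <- 300
  ph <- make_cov_table(n, seed = 4)
  gt <- data.frame(sample_id = ph$sample_id, gap = rnorm(n))
  ph$y <- rnorm(n)
  ph$constant <- 1
  expect_warning(out <- association_scan(gt, ph, c("y", "constant")),
                 "single class")
  expect_equal(out$phenotype, "y")
  sub <- association_scan(gt, ph, "y", subset = function(d) d$age > 55)
  expect_equal(sub$n, sum(ph$age > 55))
})

test_that("Cox models exclude prevalent cases and estimate a known hazard ratio", {
  n <- 3000
  ph <- make_cov_table(n, seed = 5)
  set.seed(6)
  gap <- rnorm(n, 0, 3)
  gt <- data.frame(sample_id = ph$sample_id, gap = gap)
  lam <- 0.03 * exp(0.12 * gap)
  t_ev <- rexp(n) / lam
  oc <- data.frame(sample_id = ph$sample_id, endpoint = "d",
                   prevalent = c(rep(TRUE, 100), rep(FALSE, n - 100)),
                   event = t_ev <= 10, time = pmin(t_ev, 10))
  oc$event[oc$prevalent] <- FALSE
  res <- cox_hazard(gt, oc, ph, tier = 2)
  expect_equal(res$n, n - 100)
  expect_equal(res$events, sum(oc$event[!oc$prevalent]))
  expect_lt(abs(res$log_hr - 0.12), 0.02)
  expect_true(res$ci_lo < res$hr && res$hr < res$ci_hi)
  expect_false(res$low_power)
  # BH across endpoints within the tier
  oc2 <- oc; oc2$endpoint <- "e"
  both <- cox_hazard(gt, rbind(oc, oc2), ph, tier = 1)
  expect_equal(both$q, bh_fdr(both$p))
})

test_that("few events raise the low-power flag", {
  n <- 200
  ph <- make_cov_table(n, seed = 7)
  gt <- data.frame(sample_id = ph$sample_id, gap = rnorm(n))
  set.seed(8)
  oc <- data.frame(sample_id = ph$sample_id, endpoint = "rare",
                   prevalent = FALSE,
                   event = c(rep(TRUE, 5), rep(FALSE, n - 5)),
                   time = runif(n, 1, 10))
  res <- cox_hazard(gt, oc, ph, tier = 1)
  expect_true(res$low_power)
})

test_that("KM cumulative incidence matches the hand product-limit estimate", {
  # 50 samples, deciles of 5; craft the top decile's five records by hand
  n <- 50
  ids <- sprintf("S%05d", 1:n)
  gt <- data.frame(sample_id = ids, gap = seq_len(n) + 0)
  ph <- data.frame(sample_id = ids, age = rep(55, n))
  set.seed(9)
  oc <- data.frame(sample_id = ids, endpoint = "d", prevalent = FALSE,
                   event = FALSE, time = 10)
  top <- 46:50  # gaps 46..50 form decile 10
  oc$time[top] <- c(1, 2, 2, 4, 9)
  oc$event[top] <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  oc$event[1:5] <- c(TRUE, FALSE, FALSE, FALSE, FALSE)
  oc$time[1:5] <- c(3, 10, 10, 10, 10)
  km <- km_incidence_by_decile(gt, oc, ph, deciles = c("bottom", "top"))
  ref <- hand_km(oc$time[top], oc$event[top])
  kt <- km[km$group == "top" & km$n_events > 0, ]
  expect_equal(kt$time, ref$time)
  expect_equal(kt$incidence, ref$incidence, tolerance = 1e-12)
  # plotting axis: group mean recruitment age plus follow-up time
  expect_equal(kt$age, 55 + ref$time)
  kb <- km[km$group == "bottom" & km$n_events > 0, ]
  expect_equal(kb$incidence, hand_km(oc$time[1:5], oc$event[1:5])$incidence)
  expect_error(km_incidence_by_decile(gt, transform(oc, endpoint = ids), ph),
               "one endpoint")
})

test_that("zero-event decile groups warn and return a flat curve", {
  n <- 50
  ids <- sprintf("S%05d", 1:n)
  gt <- data.frame(sample_id = ids, gap = seq_len(n) + 0)
  ph <- data.frame(sample_id = ids, age = rep(60, n))
  oc <- data.frame(sample_id = ids, endpoint = "d", prevalent = FALSE,
                   event = rep(c(TRUE, FALSE), c(25, 25)), time = 5)
  expect_warning(km <- km_incidence_by_decile(gt, oc, ph, deciles = "top"),
                 "zero events")
  expect_equal(km$incidence, 0)
})

test_that("fold risk exponentiates the hazard ratio over the contrast", {
  expect_equal(fold_risk(1.10, 6.3), 1.10^6.3)
  expect_equal(fold_risk(2, 0), 1)
  expect_equal(fold_risk(1, 100), 1)
  expect_error(fold_risk(-1, 2), "positive")
  expect_error(fold_risk(0, 2), "positive")
})

test_that("multimorbidity trend pools four or more diagnoses and reports exact means", {
  ids <- sprintf("S%05d", 1:12)
  gt <- data.frame(sample_id = ids,
                   gap = c(0, 2, 1, 3, 2, 4, 3, 5, 4, 6, 8, 10))
  cnt <- setNames(c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4, 6, 7), ids)
  out <- multimorbidity_trend(gt, cnt)
  expect_equal(as.character(out$category), c("0", "1", "2", "3", "4+"))
  expect_equal(out$n, c(2, 2, 2, 2, 4))
  expect_equal(out$mean_gap, c(1, 2, 3, 4, 7))
  expect_true(all(is.finite(out$lo)))
  expect_true(all(out$lo < out$mean_gap & out$mean_gap < out$hi))
  expect_error(multimorbidity_trend(gt, setNames(-1, ids[1])), ">= 0")
  # age stratification
  age <- setNames(c(rep(45, 6), rep(65, 6)), ids)
  st <- multimorbidity_trend(gt, cnt, age = age, age_breaks = c(39, 55, 71))
  expect_equal(length(unique(st$stratum)), 2)
  expect_equal(sum(st$n), 12)
})
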