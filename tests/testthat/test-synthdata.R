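test_that("identical configs generate identical cohorts", {
  cfg <- synth_config(80, 30, 5, seed = 7,
                      outcome_specs = list(outcome_spec("d", 0.02)),
                      phenotype_specs = list(phenotype_spec("f", loading = 0.1)))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(synth_config(80, 30, 5, seed = 8))
  expect_false(identical(a$proteins, c2$proteins))
})

test_that("cohort structure matches the configuration", {
  cfg <- synth_config(60, 25, 6, missing_rate = 0, seed = 3,
                      outcome_specs = list(outcome_spec("d", 0.05, log_hr = 0.1,
                                                        prevalence = 0.1)),
                      phenotype_specs = list(
                        phenotype_spec("cont", "continuous", 0.2),
                        phenotype_spec("bin", "binary", 0.3)))
  co <- generate_cohort(cfg)
  expect_equal(dim(co$proteins), c(60, 25))
  expect_equal(rownames(co$proteins), sprintf("S%05d", 1:60))
  expect_equal(colnames(co$proteins), sprintf("PROT%04d", 1:25))
  expect_equal(unname(co$truth$aging_flag), c(rep(TRUE, 6), rep(FALSE, 19)))
  expect_true(all(co$truth$beta[!co$truth$aging_flag] == 0))
  expect_equal(length(co$truth$delta), 60)
  expect_true(all(co$phenotypes$age >= 39 & co$phenotypes$age <= 71))
  expect_true(all(co$phenotypes$bin %in% 0:1))
  expect_equal(co$outcomes$endpoint, rep("d", 60))
  expect_true(all(!co$outcomes$event[co$outcomes$prevalent]))
})

test_that("protein trajectories recover the planted slopes", {
  cfg <- synth_config(2000, 10, 10, slope_scale = 0, nonlinear_fraction = 0,
                      aging_rate_sd = 0, noise_sd = 0.1, missing_rate = 0,
                      slopes = seq(0.02, 0.2, length.out = 10), seed = 5)
  co <- generate_cohort(cfg)
  fitted <- vapply(1:10, function(j) {
    unname(coef(lm(co$proteins[, j] ~ co$phenotypes$age))[2])
  }, numeric(1))
  expect_equal(fitted, seq(0.02, 0.2, length.out = 10), tolerance = 0.02)
})

test_that("nonlinear aging proteins show the configured curvature", {
  cfg <- synth_config(4000, 5, 5, slope_scale = 0, nonlinear_fraction = 0.4,
                      aging_rate_sd = 0, noise_sd = 0.05, missing_rate = 0,
                      slopes = rep(0.1, 5), seed = 9)
  co <- generate_cohort(cfg)
  expect_equal(unname(co$truth$quad), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  quad_coef <- function(j) {
    a <- co$phenotypes$age
    unname(coef(lm(co$proteins[, j] ~ a + I(a^2)))[3])
  }
  # kappa = beta / width = 0.1 / 32
  expect_lt(abs(quad_coef(1) - 0.1 / 32), 0.3 * 0.1 / 32)
  expect_lt(abs(quad_coef(3)), 0.2 * 0.1 / 32)
})

test_that("MCAR missingness hits the requested rate and below-detection masks the lowest values", {
  set.seed(1)
  M <- named_matrix(rnorm(5000), 100, 50)
  out <- apply_missingness(M, 0.1, "mcar", seed = 2)
  expect_lt(abs(mean(is.na(out)) - 0.1), 0.015)
  bd <- apply_missingness(M, 0.2, "below_detection")
  expect_equal(sum(is.na(bd[, 1])), 20)
  cutoff <- sort(M[, 1])[20]
  expect_true(all(M[is.na(bd[, 1]), 1] <= cutoff))
  expect_identical(apply_missingness(M, 0), M)
})

test_that("survival simulation matches the exponential closed form", {
  cfg <- synth_config(20000, 1, 0, aging_rate_sd = 0, missing_rate = 0,
                      seed = 2)
  co <- generate_cohort(cfg)
  sp <- outcome_spec("d", baseline_hazard = 0.03, log_hr = 0, horizon = 10)
  oc <- simulate_survival(co$truth, co$phenotypes, sp, seed = 4)
  expect_lt(abs(mean(oc$event) - (1 - exp(-0.03 * 10))), 0.01)
  expect_true(all(oc$time <= 10))
  expect_true(all(oc$time[oc$event] < 10 + 1e-12))
  # higher latent deviation raises the event rate when log_hr > 0
  cfg2 <- synth_config(20000, 1, 0, aging_rate_sd = 3, missing_rate = 0,
                       seed = 2)
  co2 <- generate_cohort(cfg2)
  sp2 <- outcome_spec("d", 0.03, log_hr = 0.2, horizon = 10)
  oc2 <- simulate_survival(co2$truth, co2$phenotypes, sp2, seed = 4)
  d <- co2$truth$delta[oc2$sample_id]
  expect_gt(mean(oc2$event[d > 2]), mean(oc2$event[d < -2]))
})

test_that("baseline_hazard_for_rate inverts the expected event fraction", {
  lam <- baseline_hazard_for_rate(0.25, 10)
  expect_equal(lam, -log(1 - 0.25) / 10, tolerance = 1e-8)
  lam2 <- baseline_hazard_for_rate(0.2, 10, log_hr = 0.1, delta_sd = 3)
  f <- function(d) (1 - exp(-lam2 * exp(0.1 * d) * 10)) * dnorm(d, 0, 3)
  expect_equal(integrate(f, -24, 24)$value, 0.2, tolerance = 1e-6)
})

test_that("generator configuration is validated", {
  expect_error(synth_config(10, 5, 6), "n_aging_proteins")
  expect_error(synth_config(10, 5, 2, age_range = c(70, 40)), "age_range")
  expect_error(synth_config(10, 5, 2, slopes = 1:3), "slopes")
  expect_error(outcome_spec("d", -1), "baseline_hazard")
  expect_error(outcome_spec("d", 0.1, prevalence = 2), "prevalence")
  expect_error(phenotype_spec("p", "weird"))
})
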