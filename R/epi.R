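#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment (monotone in p rank, capped at 1), delegated to
#' [stats::p.adjust()].
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return q values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    fail("p values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

# covariate formulas for the three adjustment tiers
tier_covariates <- function(tier) {
  switch(as.character(tier),
    "1" = c("age", "sex"),
    "2" = c("age", "sex", "deprivation", "center", "activity", "smoking"),
    "3" = c("age", "sex", "deprivation", "center", "activity", "smoking",
            "bmi", "hypertension"),
    fail("`tier` must be 1, 2 or 3"))
}

#' Covariate-adjusted association scan of the age gap against phenotypes
#'
#' For each phenotype, fits a linear (continuous) or logistic (binary)
#' regression of the phenotype on the age gap plus covariates, and adjusts
#' the gap p values across the scan by Benjamini-Hochberg.
#'
#' @param gap_table gap table from [oof_predict_age()] / [compute_age_gap()].
#' @param phenotypes data.frame with `sample_id`, the covariates and the
#'   phenotype columns.
#' @param phenotype_names columns of `phenotypes` to test.
#' @param covariates covariate column names (default: age, sex, deprivation,
#'   center, activity and smoking, the scan's adjustment set).
#' @param subset optional logical vector (aligned with `phenotypes` rows) or
#'   predicate function on `phenotypes` selecting an analysis subset (e.g.
#'   disease-free, never-smokers, normal BMI).
#' @return data.frame: phenotype, family, beta, se, p, q, n.
#' @export
association_scan <- function(gap_table, phenotypes, phenotype_names,
                             covariates = c("age", "sex", "deprivation",
                                            "center", "activity", "smoking"),
                             subset = NULL) {
  df <- merge(gap_table[, c("sample_id", "gap")], phenotypes,
              by = "sample_id")
  if (!is.null(subset)) {
    keep <- if (is.function(subset)) subset(df) else {
      subset[match(df$sample_id, phenotypes$sample_id)]
    }
    df <- df[keep, , drop = FALSE]
  }
  if (var(df$gap) == 0) fail("gap has zero variance in the analysis subset")
  rows <- lapply(phenotype_names, function(ph) {
    y <- df[[ph]]
    is_binary <- length(unique(y[!is.na(y)])) <= 2
    if (is_binary && length(unique(y[!is.na(y)])) < 2) {
      warning("phenotype ", ph, " has a single class; skipped", call. = FALSE)
      return(NULL)
    }
    fml <- stats::reformulate(c("gap", covariates), response = ph)
    fit <- if (is_binary) {
      stats::glm(fml, data = df, family = stats::binomial())
    } else {
      lm(fml, data = df)
    }
    cf <- summary(fit)$coefficients
    data.frame(phenotype = ph,
               family = if (is_binary) "logistic" else "linear",
               beta = cf["gap", 1], se = cf["gap", 2],
               p = cf["gap", 4], n = length(fit$residuals),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) fail("no testable phenotypes")
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out[, c("phenotype", "family", "beta", "se", "p", "q", "n")]
}

#' Tiered Cox proportional-hazards models of the age gap on incident outcomes
#'
#' Excludes prevalent cases per endpoint, fits a Cox model (Efron ties) of
#' the survival outcome on the age gap plus the tier's covariates, and
#' reports the hazard ratio per gap-year with BH-adjusted p values across
#' endpoints within the tier. Tier 1 adjusts for age and sex; tier 2 adds
#' deprivation, center, activity and smoking; tier 3 adds BMI and
#' hypertension.
#'
#' @param gap_table gap table covering the outcome samples.
#' @param outcomes long outcome table (sample_id, endpoint, prevalent,
#'   event, time).
#' @param phenotypes covariate table keyed by sample_id.
#' @param tier 1, 2 or 3.
#' @return data.frame: endpoint, tier, hr, ci_lo, ci_hi, log_hr, se, p, q,
#'   events, n, low_power flag (fewer than 10 events after exclusion).
#' @export
cox_hazard <- function(gap_table, outcomes, phenotypes, tier = 1) {
  covs <- tier_covariates(tier)
  rows <- lapply(split(outcomes, outcomes$endpoint), function(oc) {
    oc <- oc[!oc$prevalent, , drop = FALSE]
    df <- merge(merge(oc, gap_table[, c("sample_id", "gap")],
                      by = "sample_id"),
                phenotypes, by = "sample_id")
    n_events <- sum(df$event)
    low_power <- n_events < 10
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~ gap +", paste(covs, collapse = " + ")))
    fit <- survival::coxph(fml, data = df, ties = "efron")
    cf <- summary(fit)$coefficients
    ci <- summary(fit)$conf.int
    data.frame(endpoint = oc$endpoint[1], tier = tier,
               hr = cf["gap", "exp(coef)"],
               ci_lo = ci["gap", "lower .95"],
               ci_hi = ci["gap", "upper .95"],
               log_hr = cf["gap", "coef"], se = cf["gap", "se(coef)"],
               p = cf["gap", "Pr(>|z|)"], events = n_events,
               n = nrow(df), low_power = low_power,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out[, c("endpoint", "tier", "hr", "ci_lo", "ci_hi", "log_hr", "se", "p",
          "q", "events", "n", "low_power")]
}

#' Kaplan-Meier cumulative incidence by age-gap decile
#'
#' Computes gap deciles on the analysis sample after excluding prevalent
#' cases, fits a Kaplan-Meier curve per requested decile group, and returns
#' cumulative incidence (1 minus the product-limit survival) with 95%
#' confidence bands. The `age` column maps the follow-up axis onto age at
#' recruitment for plotting (group mean recruitment age plus follow-up
#' time); estimation itself uses follow-up time.
#'
#' @param gap_table gap table covering the outcome samples.
#' @param outcomes outcome table for a single endpoint.
#' @param phenotypes table with sample_id and age at recruitment.
#' @param deciles which decile groups to return: indices 1-10 or the labels
#'   "bottom" (1st), "median" (5th) and "top" (10th).
#' @return data.frame: group, time, age, incidence, lo, hi, n_events.
#' @export
km_incidence_by_decile <- function(gap_table, outcomes, phenotypes,
                                   deciles = c("bottom", "median", "top")) {
  if (length(unique(outcomes$endpoint)) > 1) {
    fail("one endpoint at a time")
  }
  oc <- outcomes[!outcomes$prevalent, , drop = FALSE]
  df <- merge(merge(oc, gap_table[, c("sample_id", "gap")], by = "sample_id"),
              phenotypes[, c("sample_id", "age")], by = "sample_id")
  dec_idx <- vapply(deciles, function(d) {
    if (is.numeric(d)) as.integer(d)
    else switch(d, bottom = 1L, median = 5L, top = 10L,
                fail("unknown decile label: ", d))
  }, integer(1))
  br <- quantile(df$gap, 0:10 / 10)
  df$decile <- cut(df$gap, br, include.lowest = TRUE, labels = FALSE)
  out <- lapply(seq_along(dec_idx), function(i) {
    sub <- df[df$decile == dec_idx[i], , drop = FALSE]
    lab <- as.character(deciles[i])
    if (!nrow(sub)) return(NULL)
    if (sum(sub$event) == 0) {
      warning("decile group ", lab, " has zero events", call. = FALSE)
      return(data.frame(group = lab, time = max(sub$time),
                        age = mean(sub$age) + max(sub$time), incidence = 0,
                        lo = 0, hi = 0, n_events = 0L,
                        stringsAsFactors = FALSE))
    }
    km <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub,
                            conf.type = "log")
    data.frame(group = lab, time = km$time,
               age = mean(sub$age) + km$time,
               incidence = 1 - km$surv,
               lo = 1 - km$upper, hi = 1 - km$lower,
               n_events = km$n.event, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fold increase in risk over a gap contrast
#'
#' Exponentiates a per-gap-year hazard ratio over a contrast of
#' `delta_years`: `fold = hr ^ delta_years`. With the published
#' fully-adjusted chronic kidney disease HR of 1.10 per gap-year and the
#' top-5% mean gap of 6.3 years this gives 1.10^6.3 = 1.8 (one decimal).
#'
#' @param hr hazard ratio per gap-year (> 0).
#' @param delta_years size of the gap contrast in years.
#' @return the fold risk.
#' @export
fold_risk <- function(hr, delta_years) {
  if (!is.finite(hr) || hr <= 0) fail("`hr` must be positive")
  check_number(delta_years, "delta_years")
  hr^delta_years
}

#' Mean age gap by lifetime-diagnosis count
#'
#' Groups samples by number of lifetime diagnoses (counts of four or more
#' pooled into "4+"), optionally within age strata, and reports the mean gap
#' with a normal-approximation 95% confidence interval per category.
#'
#' @param gap_table gap table.
#' @param diagnosis_counts named (by sample_id) non-negative integer vector.
#' @param age optional named numeric vector of ages for stratification.
#' @param age_breaks breakpoints defining age strata (used with `age`).
#' @return data.frame: stratum, category, n, mean_gap, lo, hi.
#' @export
multimorbidity_trend <- function(gap_table, diagnosis_counts, age = NULL,
                                 age_breaks = NULL) {
  if (any(diagnosis_counts < 0)) fail("diagnosis counts must be >= 0")
  cnt <- diagnosis_counts[gap_table$sample_id]
  if (anyNA(cnt)) fail("diagnosis counts missing for some samples")
  cat <- ifelse(cnt >= 4, "4+", as.character(cnt))
  cat <- factor(cat, levels = c("0", "1", "2", "3", "4+"))
  stratum <- if (is.null(age)) factor(rep("all", nrow(gap_table))) else {
    cut(age[gap_table$sample_id], age_breaks, include.lowest = TRUE)
  }
  rows <- list()
  for (s in levels(stratum)) {
    for (cc in levels(cat)) {
      idx <- which(stratum == s & cat == cc)
      if (!length(idx)) next
      g <- gap_table$gap[idx]
      se <- if (length(g) > 1) sd(g) / sqrt(length(g)) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        stratum = s, category = cc, n = length(g), mean_gap = mean(g),
        lo = mean(g) - qnorm(0.975) * se, hi = mean(g) + qnorm(0.975) * se,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    warning("no non-empty strata", call. = FALSE)
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
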