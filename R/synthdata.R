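#' Configuration for the synthetic proteomic aging cohort
#'
#' Defines a cohort in which each individual carries a latent aging deviation
#' \eqn{\delta_i} (in years) on top of chronological age. Aging proteins drift
#' linearly (optionally quadratically) in biological age
#' \eqn{age_i + \delta_i} on the NPX-like log2 scale, outcomes are drawn with
#' hazards that rise with \eqn{\delta_i}, and phenotypes load on
#' \eqn{\delta_i}. The generator is the ground-truth bench for every
#' downstream stage: the clock's out-of-fold age gap is an estimate of
#' \eqn{\delta_i}.
#'
#' @param n_samples number of individuals.
#' @param n_proteins total proteins; the first `n_aging_proteins` carry age
#'   signal, the rest are pure noise.
#' @param n_aging_proteins number of age-informative proteins.
#' @param age_range recruitment age range in years, drawn uniformly.
#' @param slope_scale s.d. of per-protein age slopes (NPX units per year).
#' @param nonlinear_fraction fraction of aging proteins given an additional
#'   centered quadratic term in biological age.
#' @param aging_rate_sd s.d. of the latent deviation \eqn{\delta_i} (years).
#' @param noise_sd residual NPX s.d. per protein.
#' @param missing_rate fraction of cells masked (MCAR) by [generate_cohort()].
#' @param outcome_specs list of [outcome_spec()] entries.
#' @param phenotype_specs list of [phenotype_spec()] entries.
#' @param slopes optional explicit numeric vector of slopes for the aging
#'   proteins (length `n_aging_proteins`), overriding the random draw.
#' @param intercepts optional explicit per-protein intercepts (length
#'   `n_proteins`), overriding the random draw.
#' @param seed integer RNG seed; identical configs give identical cohorts.
#' @return a `synth_config` list, validated.
#' @export
synth_config <- function(n_samples, n_proteins, n_aging_proteins,
                         age_range = c(39, 71), slope_scale = 0.03,
                         nonlinear_fraction = 0.2, aging_rate_sd = 3,
                         noise_sd = 0.3, missing_rate = 0.1,
                         outcome_specs = list(), phenotype_specs = list(),
                         slopes = NULL, intercepts = NULL, seed = 1L) {
  check_number(n_samples, "n_samples", lo = 1)
  check_number(n_proteins, "n_proteins", lo = 1)
  check_number(n_aging_proteins, "n_aging_proteins", lo = 0, hi = n_proteins)
  if (length(age_range) != 2 || !all(is.finite(age_range)) ||
      age_range[1] >= age_range[2]) {
    fail("`age_range` must be finite (min, max) with min < max")
  }
  check_number(slope_scale, "slope_scale", lo = 0)
  check_number(nonlinear_fraction, "nonlinear_fraction", lo = 0, hi = 1)
  check_number(aging_rate_sd, "aging_rate_sd", lo = 0)
  check_number(noise_sd, "noise_sd", lo = 0)
  check_number(missing_rate, "missing_rate", lo = 0, hi = 1)
  check_number(seed, "seed")
  if (!is.null(slopes) && length(slopes) != n_aging_proteins) {
    fail("`slopes` must have length n_aging_proteins")
  }
  if (!is.null(intercepts) && length(intercepts) != n_proteins) {
    fail("`intercepts` must have length n_proteins")
  }
  structure(list(
    n_samples = as.integer(n_samples), n_proteins = as.integer(n_proteins),
    n_aging_proteins = as.integer(n_aging_proteins),
    age_range = as.numeric(age_range), slope_scale = slope_scale,
    nonlinear_fraction = nonlinear_fraction, aging_rate_sd = aging_rate_sd,
    noise_sd = noise_sd, missing_rate = missing_rate,
    outcome_specs = outcome_specs, phenotype_specs = phenotype_specs,
    slopes = slopes, intercepts = intercepts, seed = as.integer(seed)
  ), class = "synth_config")
}

#' Survival endpoint specification for the generator
#'
#' @param name endpoint label.
#' @param baseline_hazard events per person-year at \eqn{\delta = 0}; must be
#'   positive.
#' @param log_hr log hazard ratio per year of latent deviation \eqn{\delta}.
#' @param prevalence fraction flagged as prevalent at baseline.
#' @param horizon administrative censoring time in years.
#' @param shape Weibull shape (1 = exponential, the default, which keeps a
#'   closed-form oracle for recovery tests).
#' @param prevalence_mode `"independent"` (default) or `"delta"`, in which
#'   case prevalence odds scale with `exp(log_hr * delta)`.
#' @export
outcome_spec <- function(name, baseline_hazard, log_hr = 0, prevalence = 0,
                         horizon = 10, shape = 1,
                         prevalence_mode = c("independent", "delta")) {
  check_number(baseline_hazard, "baseline_hazard", lo = 1e-12)
  check_number(log_hr, "log_hr")
  check_number(prevalence, "prevalence", lo = 0, hi = 1)
  if (!is.finite(horizon) || horizon <= 0) fail("`horizon` must be > 0")
  check_number(shape, "shape", lo = 1e-12)
  list(name = name, baseline_hazard = baseline_hazard, log_hr = log_hr,
       prevalence = prevalence, horizon = horizon, shape = shape,
       prevalence_mode = match.arg(prevalence_mode))
}

#' Phenotype specification for the generator
#'
#' Continuous phenotypes are `loading * delta + Normal(0, noise^2)`; binary
#' phenotypes are Bernoulli with logit `loading * delta + Normal(0, noise^2)`.
#'
#' @param name phenotype label.
#' @param family `"continuous"` or `"binary"`.
#' @param loading effect of one latent \eqn{\delta}-year on the phenotype
#'   (linear scale or log-odds scale respectively).
#' @param noise residual s.d.
#' @export
phenotype_spec <- function(name, family = c("continuous", "binary"),
                           loading = 0, noise = 1) {
  family <- match.arg(family)
  check_number(loading, "loading")
  check_number(noise, "noise", lo = 0)
  list(name = name, family = family, loading = loading, noise = noise)
}

# fixed multinomial probabilities for the categorical covariates
.covariate_probs <- list(
  center = c(A = 0.40, B = 0.35, C = 0.25),
  activity = c(low = 0.30, moderate = 0.45, high = 0.25),
  smoking = c(never = 0.55, previous = 0.33, current = 0.12)
)

#' Generate a synthetic proteomic aging cohort with known ground truth
#'
#' Draws ages uniformly over the configured range and a latent per-individual
#' aging deviation \eqn{\delta_i \sim N(0, \sigma_\delta^2)}; protein values
#' follow \eqn{x_{ip} = \mu_p + \beta_p (age_i + \delta_i) + q_p(\cdot) +
#' \epsilon_{ip}} where \eqn{q_p} is a centered quadratic term for the flagged
#' nonlinear aging proteins. Missingness (MCAR at `missing_rate`), covariates,
#' phenotypes and survival outcomes are generated alongside.
#'
#' @param config a [synth_config()].
#' @return list with `proteins` (samples x proteins matrix, NPX-like, with
#'   missingness), `phenotypes` (data.frame: sample_id, age, sex, deprivation,
#'   center, activity, smoking, bmi, hypertension, plus configured
#'   phenotypes), `truth` (list: `beta`, `aging_flag`, `quad`, `delta`,
#'   `gamma`), and `outcomes` (long data.frame from [simulate_survival()],
#'   one block per configured endpoint, or NULL).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config")) fail("`config` must be a synth_config")
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_proteins
  ids <- sprintf("S%05d", seq_len(n))
  prots <- sprintf("PROT%04d", seq_len(p))

  age <- runif(n, config$age_range[1], config$age_range[2])
  delta <- rnorm(n, 0, config$aging_rate_sd)
  bioage <- age + delta

  aging_flag <- seq_len(p) <= config$n_aging_proteins
  beta <- numeric(p)
  if (config$n_aging_proteins > 0) {
    beta[aging_flag] <- if (is.null(config$slopes)) {
      rnorm(config$n_aging_proteins, 0, config$slope_scale)
    } else config$slopes
  }
  n_quad <- floor(config$nonlinear_fraction * config$n_aging_proteins)
  quad <- logical(p)
  quad[seq_len(n_quad)] <- TRUE
  mu <- if (is.null(config$intercepts)) rnorm(p, 0, 1) else config$intercepts

  width <- diff(config$age_range)
  mid <- mean(config$age_range)
  cb <- bioage - mid
  X <- matrix(rnorm(n * p, 0, config$noise_sd), n, p,
              dimnames = list(ids, prots))
  X <- sweep(X, 2, mu, "+") + outer(bioage, beta)
  if (n_quad > 0) {
    kappa <- beta / width
    qterm <- outer(cb^2 - width^2 / 12, kappa * quad)
    X <- X + qterm
  }

  pheno <- data.frame(
    sample_id = ids, age = age,
    sex = rbinom(n, 1, 0.5),
    deprivation = rnorm(n),
    center = factor(sample(names(.covariate_probs$center), n, TRUE,
                           .covariate_probs$center),
                    levels = names(.covariate_probs$center)),
    activity = factor(sample(names(.covariate_probs$activity), n, TRUE,
                             .covariate_probs$activity),
                      levels = names(.covariate_probs$activity)),
    smoking = factor(sample(names(.covariate_probs$smoking), n, TRUE,
                            .covariate_probs$smoking),
                     levels = names(.covariate_probs$smoking)),
    bmi = rnorm(n, 27, 4.8),
    hypertension = rbinom(n, 1, 0.3),
    stringsAsFactors = FALSE
  )
  for (ps in config$phenotype_specs) {
    lin <- ps$loading * delta
    pheno[[ps$name]] <- if (ps$family == "continuous") {
      lin + rnorm(n, 0, ps$noise)
    } else {
      rbinom(n, 1, plogis(lin + rnorm(n, 0, ps$noise)))
    }
  }

  truth <- list(
    beta = setNames(beta, prots), aging_flag = setNames(aging_flag, prots),
    quad = setNames(quad, prots), delta = setNames(delta, ids),
    gamma = vapply(config$outcome_specs, function(s) s$log_hr, numeric(1))
  )
  if (length(config$outcome_specs)) {
    names(truth$gamma) <- vapply(config$outcome_specs, `[[`, "", "name")
  }

  if (config$missing_rate > 0) {
    X <- apply_missingness(X, config$missing_rate, mode = "mcar")
  }

  outcomes <- NULL
  if (length(config$outcome_specs)) {
    outcomes <- do.call(rbind, lapply(config$outcome_specs, function(s) {
      simulate_survival(truth, pheno, s)
    }))
    rownames(outcomes) <- NULL
  }

  list(proteins = X, phenotypes = pheno, truth = truth, outcomes = outcomes)
}

#' Simulate a survival endpoint from the latent aging deviation
#'
#' Event times are Weibull (exponential by default) with individual rate
#' \eqn{\lambda_0 \exp(\gamma \delta_i)}, administratively censored at the
#' horizon. Prevalent flags are assigned at the stated fraction, independent
#' of \eqn{\delta} by default; prevalent records never carry an incident
#' event.
#'
#' @param truth `truth` component of [generate_cohort()] (needs `delta`).
#' @param phenotypes phenotype table with `sample_id` matching `truth$delta`.
#' @param spec an [outcome_spec()].
#' @param seed optional seed; NULL continues the current RNG stream.
#' @return data.frame: sample_id, endpoint, prevalent, event, time.
#' @export
simulate_survival <- function(truth, phenotypes, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (spec$horizon <= 0) fail("`horizon` must be > 0")
  ids <- phenotypes$sample_id
  delta <- truth$delta[ids]
  if (anyNA(delta)) fail("phenotype sample ids missing from truth$delta")
  n <- length(ids)
  rate <- spec$baseline_hazard * exp(spec$log_hr * delta)
  t_event <- (rexp(n) / rate)^(1 / spec$shape)
  event <- t_event <= spec$horizon
  time <- pmin(t_event, spec$horizon)
  prev_p <- if (spec$prevalence_mode == "delta" && spec$prevalence > 0) {
    plogis(log(spec$prevalence / (1 - spec$prevalence)) + spec$log_hr * delta)
  } else rep(spec$prevalence, n)
  prevalent <- rbinom(n, 1, prev_p) == 1
  event[prevalent] <- FALSE
  time[prevalent] <- spec$horizon
  data.frame(sample_id = ids, endpoint = spec$name, prevalent = prevalent,
             event = event, time = time, stringsAsFactors = FALSE)
}

#' Choose a baseline hazard hitting a target event fraction
#'
#' Solves \eqn{E_\delta[1 - \exp(-\lambda_0 e^{\gamma\delta} H)] = target}
#' over \eqn{\delta \sim N(0, \sigma_\delta^2)} by numerical integration, so
#' test designs can state event fractions instead of raw hazards.
#'
#' @param target_rate desired expected event fraction in (0, 1).
#' @param horizon follow-up horizon in years.
#' @param log_hr log-HR per delta-year.
#' @param delta_sd s.d. of the latent deviation.
#' @export
baseline_hazard_for_rate <- function(target_rate, horizon, log_hr = 0,
                                     delta_sd = 0) {
  check_number(target_rate, "target_rate", lo = 1e-6, hi = 1 - 1e-6)
  expected <- function(lam) {
    if (delta_sd == 0 || log_hr == 0) {
      return(1 - exp(-lam * horizon))
    }
    f <- function(d) {
      (1 - exp(-lam * exp(log_hr * d) * horizon)) * dnorm(d, 0, delta_sd)
    }
    stats::integrate(f, -8 * delta_sd, 8 * delta_sd)$value
  }
  stats::uniroot(function(l) expected(l) - target_rate,
                 interval = c(1e-10, 100), tol = 1e-10)$root
}

#' @importFrom stats dnorm
NULL

#' Mask protein values as missing
#'
#' MCAR masks each cell independently with probability `rate`;
#' `below_detection` masks the lowest `round(rate * n)` values within each
#' protein, mimicking censoring below an assay's limit of detection.
#'
#' @param matrix samples-by-proteins numeric matrix.
#' @param rate fraction in \[0, 1\].
#' @param mode `"mcar"` or `"below_detection"`.
#' @param seed optional seed for the MCAR draw.
#' @return the matrix with masked cells set to NA.
#' @export
apply_missingness <- function(matrix, rate, mode = c("mcar", "below_detection"),
                              seed = NULL) {
  check_protein_matrix(matrix)
  check_number(rate, "rate", lo = 0, hi = 1)
  mode <- match.arg(mode)
  if (rate == 0) return(matrix)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "mcar") {
    mask <- matrix(rbinom(length(matrix), 1, rate) == 1,
                   nrow(matrix), ncol(matrix))
    matrix[mask] <- NA_real_
  } else {
    k <- round(rate * nrow(matrix))
    if (k > 0) {
      for (j in seq_len(ncol(matrix))) {
        ord <- order(matrix[, j], na.last = NA)
        matrix[ord[seq_len(min(k, length(ord)))], j] <- NA_real_
      }
    }
  }
  matrix
}
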