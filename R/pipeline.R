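#' Pipeline configuration
#'
#' One declarative configuration drives the whole simulate - preprocess -
#' clock - select - epi - network run. Stage toggles control what executes;
#' a stage whose dependency is disabled raises an error naming the missing
#' stage. A single `seed` is fanned out to deterministic per-stage seeds.
#'
#' @param n_samples,n_proteins,n_aging_proteins,noise_sd,aging_rate_sd,
#'   slope_scale,missing_rate generator settings, see [synth_config()].
#' @param stages named logical vector of stage toggles.
#' @param folds CV folds for out-of-fold prediction.
#' @param boruta_trials models per Boruta iteration.
#' @param selection_nrounds boosting rounds inside selection fits.
#' @param retain retained-performance fraction for the reduced panel.
#' @param tiers Cox adjustment tiers to fit.
#' @param network_threshold interaction threshold; NULL picks the 90th
#'   percentile of off-diagonal interaction weights.
#' @param seed run seed.
#' @export
pipeline_config <- function(n_samples = 300, n_proteins = 50,
                            n_aging_proteins = 10, noise_sd = 0.3,
                            aging_rate_sd = 3, slope_scale = 0.05,
                            missing_rate = 0.05,
                            stages = c(simulate = TRUE, preprocess = TRUE,
                                       clock = TRUE, select = TRUE,
                                       epi = TRUE, network = TRUE),
                            folds = 5, boruta_trials = 3,
                            selection_nrounds = 60, retain = 0.95,
                            tiers = 1:3, network_threshold = NULL,
                            seed = 1L) {
  structure(list(
    n_samples = n_samples, n_proteins = n_proteins,
    n_aging_proteins = n_aging_proteins, noise_sd = noise_sd,
    aging_rate_sd = aging_rate_sd, slope_scale = slope_scale,
    missing_rate = missing_rate, stages = stages, folds = folds,
    boruta_trials = boruta_trials, selection_nrounds = selection_nrounds,
    retain = retain, tiers = tiers, network_threshold = network_threshold,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#' @param path config file; top-level keys override [pipeline_config()]
#'   defaults.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(vals$stages)) vals$stages <- unlist(vals$stages)
  do.call(pipeline_config, vals)
}

# deterministic FNV-1a hash of the serialized config, for provenance.
# Kept in doubles: R's bitwXor/sprintf("%x") overflow above 2^31, so the
# byte xor touches only the low 8 bits and the 32-bit modular multiply is
# done on 16-bit halves to stay within exact double-precision integers.
config_hash <- function(config) {
  bytes <- as.integer(charToRaw(jsonlite::toJSON(unclass(config),
                                                 auto_unbox = TRUE,
                                                 digits = NA)))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

require_stage <- function(config, stage, needed_by) {
  if (!isTRUE(config$stages[[stage]])) {
    fail(sprintf("stage '%s' requires stage '%s', which is disabled",
                 needed_by, stage))
  }
}

#' Run the full pipeline from one configuration
#'
#' Executes the enabled stages in dependency order, writing per-stage tables
#' under `out_dir` and returning a run bundle (paths, metrics summary,
#' provenance). Identical config and seed give identical bundles.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return a `run_bundle` list: `config`, `paths`, `metrics`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  paths <- list()
  metrics <- list()
  seed <- config$seed

  cohort <- NULL
  if (isTRUE(st[["simulate"]])) {
    scfg <- synth_config(
      n_samples = config$n_samples, n_proteins = config$n_proteins,
      n_aging_proteins = config$n_aging_proteins,
      slope_scale = config$slope_scale, noise_sd = config$noise_sd,
      aging_rate_sd = config$aging_rate_sd,
      missing_rate = config$missing_rate,
      outcome_specs = list(
        outcome_spec("disease", baseline_hazard = 0.02, log_hr = 0.15,
                     prevalence = 0.05, horizon = 10),
        outcome_spec("mortality", baseline_hazard = 0.01, log_hr = 0.10,
                     horizon = 12)),
      phenotype_specs = list(
        phenotype_spec("frailty_like", "continuous", loading = 0.15),
        phenotype_spec("telomere_like", "continuous", loading = -0.10),
        phenotype_spec("poor_health", "binary", loading = 0.20, noise = 0)),
      seed = derive_seed(seed, "simulate"))
    cohort <- generate_cohort(scfg)
    paths$proteins <- write_protein_matrix(cohort$proteins,
                                           file.path(out_dir, "proteins.csv"))
    paths$phenotypes <- write_table_csv(cohort$phenotypes,
                                        file.path(out_dir, "phenotypes.csv"))
    paths$outcomes <- write_table_csv(cohort$outcomes,
                                      file.path(out_dir, "outcomes.csv"))
    truth_tab <- data.frame(protein = names(cohort$truth$beta),
                            beta = cohort$truth$beta,
                            aging = cohort$truth$aging_flag,
                            quad = cohort$truth$quad, row.names = NULL)
    paths$truth_proteins <- write_table_csv(
      truth_tab, file.path(out_dir, "truth_proteins.csv"))
    paths$truth_samples <- write_table_csv(
      data.frame(sample_id = names(cohort$truth$delta),
                 delta = cohort$truth$delta, row.names = NULL),
      file.path(out_dir, "truth_samples.csv"))
    metrics$simulate <- list(n_samples = nrow(cohort$proteins),
                             n_proteins = ncol(cohort$proteins))
  }

  split <- norm <- NULL
  if (isTRUE(st[["preprocess"]])) {
    require_stage(config, "simulate", "preprocess")
    split <- split_cohort(rownames(cohort$proteins), 0.70,
                          derive_seed(seed, "split"))
    flt <- filter_proteins(cohort$proteins)
    imp <- impute_proteins(flt$matrices[[1]])
    norm <- normalize_npx(imp, fit_subset = split$train)
    paths$matrix <- write_protein_matrix(norm$matrix,
                                         file.path(out_dir, "normalized.csv"))
    paths$norm_params <- write_normalization_params(
      norm$params, file.path(out_dir, "normalization_params.csv"))
    paths$filter_report <- write_table_csv(
      flt$report, file.path(out_dir, "filter_report.csv"))
    metrics$preprocess <- list(n_kept = length(flt$kept),
                               n_excluded = nrow(flt$report))
  }

  model <- gap <- NULL
  ages <- NULL
  if (isTRUE(st[["clock"]])) {
    require_stage(config, "preprocess", "clock")
    ages <- setNames(cohort$phenotypes$age, cohort$phenotypes$sample_id)
    hp <- clock_hyperparams(seed = derive_seed(seed, "fit"))
    inner <- split_cohort(split$train, 0.85, derive_seed(seed, "fit"))
    model <- fit_clock(norm$matrix[inner$train, , drop = FALSE],
                       ages[inner$train], hp,
                       norm$matrix[inner$test, , drop = FALSE],
                       ages[inner$test])
    test_pred <- predict(model, norm$matrix[split$test, , drop = FALSE])
    metrics$clock <- evaluate_predictions(test_pred, ages[split$test])
    gap <- oof_predict_age(norm$matrix, ages, hp, k = config$folds,
                           seed = seed)
    metrics$clock$oof_pearson_r <-
      evaluate_predictions(gap$predicted_age, gap$age)$pearson_r
    paths$gap <- write_table_csv(gap, file.path(out_dir, "age_gap.csv"))
    paths$model <- save_clock_model(model, file.path(out_dir, "clock_model"))
  }

  panel <- NULL
  if (isTRUE(st[["select"]])) {
    require_stage(config, "clock", "select")
    hp <- clock_hyperparams(seed = derive_seed(seed, "boruta"))
    bor <- boruta_select(norm$matrix[split$train, , drop = FALSE],
                         ages[split$train], hp,
                         trials = config$boruta_trials, seed = seed,
                         nrounds = config$selection_nrounds)
    metrics$select <- list(n_selected = length(bor$selected))
    paths$boruta <- write_table_csv(bor$history,
                                    file.path(out_dir, "boruta_history.csv"))
    if (length(bor$selected) >= 6) {
      rfe <- shap_rfe(norm$matrix[split$train, , drop = FALSE],
                      ages[split$train], bor$selected, hp, k = config$folds,
                      seed = seed, nrounds = config$selection_nrounds)
      panel <- select_reduced_panel(rfe, retain = config$retain)
      paths$rfe <- write_table_csv(rfe$curve,
                                   file.path(out_dir, "rfe_curve.csv"))
      metrics$select$n_reduced <- length(panel)
    } else {
      panel <- bor$selected
      metrics$select$n_reduced <- length(panel)
    }
    writeLines(panel, file.path(out_dir, "reduced_panel.txt"))
    paths$panel <- file.path(out_dir, "reduced_panel.txt")
  }

  if (isTRUE(st[["epi"]])) {
    require_stage(config, "clock", "epi")
    assoc <- association_scan(
      gap, cohort$phenotypes,
      c("frailty_like", "telomere_like", "poor_health"))
    paths$associations <- write_table_csv(
      assoc, file.path(out_dir, "associations.csv"))
    cox <- do.call(rbind, lapply(config$tiers, function(tr) {
      cox_hazard(gap, cohort$outcomes, cohort$phenotypes, tier = tr)
    }))
    paths$cox <- write_table_csv(cox, file.path(out_dir, "cox.csv"))
    km <- km_incidence_by_decile(
      gap, cohort$outcomes[cohort$outcomes$endpoint == "disease", ],
      cohort$phenotypes)
    paths$km <- write_table_csv(km, file.path(out_dir, "km_curves.csv"))
    counts <- with(cohort$outcomes,
                   tapply(event | prevalent, sample_id, sum))
    trend <- multimorbidity_trend(gap, counts)
    paths$trend <- write_table_csv(trend, file.path(out_dir, "trend.csv"))
    metrics$epi <- list(
      n_assoc_significant = sum(assoc$q < 0.05),
      cox_tier1_hr = cox$hr[cox$tier == 1 & cox$endpoint == "disease"])
  }

  if (isTRUE(st[["network"]])) {
    require_stage(config, "clock", "network")
    require_stage(config, "select", "network")
    net_prots <- if (length(panel) >= 2) panel else model$proteins
    hp <- clock_hyperparams(seed = derive_seed(seed, "network"))
    inner <- split_cohort(split$train, 0.85, derive_seed(seed, "network"))
    nm <- fit_clock(norm$matrix[inner$train, net_prots, drop = FALSE],
                    ages[inner$train], hp,
                    norm$matrix[inner$test, net_prots, drop = FALSE],
                    ages[inner$test])
    imat <- shap_interaction_matrix(nm, norm$matrix[split$test, net_prots,
                                                    drop = FALSE])
    off <- imat$mean_abs[upper.tri(imat$mean_abs)]
    th <- if (is.null(config$network_threshold)) {
      as.numeric(quantile(off, 0.9))
    } else config$network_threshold
    net <- build_interaction_network(imat, threshold = th)
    paths$network <- write_table_csv(net$edges,
                                     file.path(out_dir, "network_edges.csv"))
    paths$degree <- write_table_csv(
      data.frame(protein = names(net$degree), degree = as.integer(net$degree),
                 row.names = NULL),
      file.path(out_dir, "network_degree.csv"))
    metrics$network <- list(n_nodes = length(net$nodes),
                            n_edges = nrow(net$edges), threshold = th)
  }

  bundle <- structure(list(
    config = config, paths = paths, metrics = metrics,
    provenance = list(config_hash = config_hash(config), seed = seed,
                      package_version = as.character(
                        utils::packageVersion("protclock")))
  ), class = "run_bundle")
  bundle_path <- file.path(out_dir, "bundle.json")
  # serialize paths relative to out_dir so identical runs into different
  # directories produce byte-identical bundles
  rel_paths <- lapply(paths, function(p) {
    sub("^/*", "", substring(as.character(p), nchar(out_dir) + 1))
  })
  jsonlite::write_json(
    list(metrics = metrics, provenance = bundle$provenance,
         paths = rel_paths),
    bundle_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bundle$paths$bundle <- bundle_path
  bundle
}

#' Write a human-readable run report
#'
#' Emits `report.txt` summarising every enabled stage's metrics; values are
#' printed exactly from the bundle so regenerating the report from the same
#' bundle is byte-identical. Missing stages are flagged as gaps rather than
#' errors.
#'
#' @param bundle a [run_pipeline()] bundle.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_report <- function(bundle, path) {
  fmt <- function(x) {
    if (is.numeric(x)) paste(format(x, digits = 10, trim = TRUE),
                             collapse = ", ")
    else paste(as.character(x), collapse = ", ")
  }
  lines <- c("proteomic age clock run report",
             paste0("config hash: ", bundle$provenance$config_hash),
             paste0("seed: ", bundle$provenance$seed), "")
  stage_names <- c("simulate", "preprocess", "clock", "select", "epi",
                   "network")
  for (sn in stage_names) {
    enabled <- isTRUE(bundle$config$stages[[sn]])
    lines <- c(lines, paste0("== ", sn, " =="))
    if (!enabled) {
      lines <- c(lines, "  (stage disabled)", "")
      next
    }
    m <- bundle$metrics[[sn]]
    if (is.null(m)) {
      lines <- c(lines, "  (no metrics recorded: gap)", "")
      next
    }
    for (nm in names(m)) {
      lines <- c(lines, paste0("  ", nm, ": ", fmt(m[[nm]])))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}
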