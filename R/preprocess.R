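#' Filter proteins by cross-cohort availability and missingness
#'
#' Retains proteins that are present in every supplied matrix and missing in
#' at most `max_missing` of samples in the reference matrix (strictly "over
#' 10%" missing is excluded under the default). Returns the filtered matrices
#' together with an exclusion report naming the reason for each drop.
#'
#' @param matrices a single samples-by-proteins matrix or a list of them
#'   (one per cohort).
#' @param max_missing maximum tolerated missing fraction in the reference.
#' @param reference index of the matrix whose missingness governs the filter.
#' @return list with `matrices` (filtered, same order), `kept` (protein ids)
#'   and `report` (data.frame: protein, reason) for exclusions.
#' @export
filter_proteins <- function(matrices, max_missing = 0.10, reference = 1L) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  if (!length(matrices)) fail("at least one matrix required")
  for (m in matrices) check_protein_matrix(m)
  check_number(max_missing, "max_missing", lo = 0, hi = 1)
  all_prots <- unique(unlist(lapply(matrices, colnames)))
  shared <- Reduce(intersect, lapply(matrices, colnames))
  report <- data.frame(protein = character(0), reason = character(0),
                       stringsAsFactors = FALSE)
  not_shared <- setdiff(all_prots, shared)
  if (length(not_shared)) {
    report <- rbind(report, data.frame(protein = not_shared,
                                       reason = "not shared",
                                       stringsAsFactors = FALSE))
  }
  ref <- matrices[[reference]]
  miss_frac <- colMeans(is.na(ref[, shared, drop = FALSE]))
  too_missing <- shared[miss_frac > max_missing]
  if (length(too_missing)) {
    report <- rbind(report, data.frame(
      protein = too_missing,
      reason = sprintf("missing fraction %.3f > %.3f",
                       miss_frac[too_missing], max_missing),
      stringsAsFactors = FALSE))
  }
  kept <- setdiff(shared, too_missing)
  if (!length(kept)) fail("no proteins survive filtering: empty intersection")
  list(matrices = lapply(matrices, function(m) m[, kept, drop = FALSE]),
       kept = kept, report = report)
}

#' Impute missing protein values
#'
#' `method = "median"` fills each protein's missing cells with its observed
#' median. `method = "chained"` runs iterative regression imputation: missing
#' cells are initialised at the median and then, for up to `max_iterations`
#' rounds, each incomplete protein is regressed on its most correlated
#' predictor proteins and its missing cells replaced by the fitted values.
#' Only proteins with at most 30% missingness serve as predictors. Observed
#' cells are never altered.
#'
#' @param matrix samples-by-proteins matrix (post-filtering).
#' @param max_iterations maximum chained rounds (default 5).
#' @param method `"chained"` or `"median"`.
#' @param n_predictors number of top-correlated predictor proteins per model.
#' @param predictor_max_missing proteins missing more than this fraction are
#'   not used as predictors.
#' @return complete matrix, identical to the input on observed cells.
#' @export
impute_proteins <- function(matrix, max_iterations = 5,
                            method = c("chained", "median"),
                            n_predictors = 10, predictor_max_missing = 0.30) {
  check_protein_matrix(matrix)
  method <- match.arg(method)
  obs_count <- colSums(!is.na(matrix))
  if (any(obs_count == 0)) {
    fail("proteins with zero observed values cannot be imputed: ",
         paste(head(colnames(matrix)[obs_count == 0], 5), collapse = ", "))
  }
  if (!anyNA(matrix)) return(matrix)

  miss <- is.na(matrix)
  med <- apply(matrix, 2, median, na.rm = TRUE)
  filled <- matrix
  for (j in which(colSums(miss) > 0)) filled[miss[, j], j] <- med[j]
  if (method == "median") return(filled)

  predictors_ok <- colMeans(miss) <= predictor_max_missing
  targets <- which(colSums(miss) > 0)
  for (iter in seq_len(max_iterations)) {
    max_change <- 0
    for (j in targets) {
      cand <- setdiff(which(predictors_ok), j)
      if (!length(cand)) next
      r <- abs(suppressWarnings(cor(filled[, j], filled[, cand])))
      r[is.na(r)] <- 0
      pred <- cand[order(r, decreasing = TRUE)][seq_len(min(n_predictors, length(cand)))]
      train <- !miss[, j]
      df <- data.frame(y = filled[train, j], filled[train, pred, drop = FALSE])
      fit <- lm(y ~ ., data = df)
      newd <- data.frame(filled[miss[, j], pred, drop = FALSE])
      new_vals <- predict(fit, newdata = newd)
      max_change <- max(max_change, max(abs(new_vals - filled[miss[, j], j])))
      filled[miss[, j], j] <- new_vals
    }
    if (max_change < 1e-6) break
  }
  filled[!miss] <- matrix[!miss]
  filled
}

#' Min-max rescale and median-center NPX values
#'
#' Per protein, maps values by `(x - min) / (max - min)` to \[0, 1\] and then
#' subtracts the post-rescale median, so each protein has median 0 and range
#' within \[-1, 1\] on the data the parameters were fitted to. When `params`
#' is supplied the stored parameters are applied unchanged (cross-cohort
#' mode). Constant proteins map to 0 with a warning.
#'
#' @param matrix complete samples-by-proteins matrix.
#' @param params optional `normalization_params` from a previous fit.
#' @param fit_subset optional sample ids to fit the parameters on (e.g. the
#'   training split); defaults to all samples.
#' @return list with `matrix` (normalized) and `params` (data.frame: protein,
#'   min, max, median).
#' @export
normalize_npx <- function(matrix, params = NULL, fit_subset = NULL) {
  check_protein_matrix(matrix, allow_missing = FALSE)
  if (is.null(params)) {
    fit <- if (is.null(fit_subset)) matrix else {
      missing_ids <- setdiff(fit_subset, rownames(matrix))
      if (length(missing_ids)) fail("fit_subset ids absent from matrix")
      matrix[fit_subset, , drop = FALSE]
    }
    mins <- apply(fit, 2, min)
    maxs <- apply(fit, 2, max)
    rng <- maxs - mins
    if (any(rng == 0)) {
      warning("constant protein(s) set to 0: ",
              paste(head(colnames(fit)[rng == 0], 5), collapse = ", "),
              call. = FALSE)
    }
    scaled_fit <- scale_minmax(fit, mins, maxs)
    meds <- apply(scaled_fit, 2, median)
    params <- structure(
      data.frame(protein = colnames(matrix), min = mins, max = maxs,
                 median = meds, row.names = NULL, stringsAsFactors = FALSE),
      class = c("normalization_params", "data.frame"))
  } else {
    idx <- match(colnames(matrix), params$protein)
    if (anyNA(idx)) fail("params lack proteins present in matrix")
    params <- params[idx, , drop = FALSE]
  }
  out <- scale_minmax(matrix, params$min, params$max)
  out <- sweep(out, 2, params$median, "-")
  list(matrix = out, params = params)
}

scale_minmax <- function(m, mins, maxs) {
  rng <- maxs - mins
  rng[rng == 0] <- 1  # constant proteins collapse to 0
  sweep(sweep(m, 2, mins, "-"), 2, rng, "/")
}

#' Run filter, imputation and normalization as one step
#'
#' Convenience wrapper preserving sample order; normalization is fitted on
#' `fit_subset` when given (leakage-safe default for split designs) or on all
#' samples (the full-cohort variant).
#'
#' @inheritParams filter_proteins
#' @inheritParams normalize_npx
#' @param method imputation method, see [impute_proteins()].
#' @return list with `matrix`, `params`, `report`.
#' @export
preprocess_cohort <- function(matrices, max_missing = 0.10,
                              method = "chained", fit_subset = NULL) {
  flt <- filter_proteins(matrices, max_missing = max_missing)
  imp <- impute_proteins(flt$matrices[[1]], method = method)
  nrm <- normalize_npx(imp, fit_subset = fit_subset)
  list(matrix = nrm$matrix, params = nrm$params, report = flt$report)
}
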