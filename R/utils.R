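#' @importFrom stats coef lm median model.matrix plogis predict qnorm quantile
#'   rbinom rexp rnorm runif sd setNames var complete.cases p.adjust pnorm cor
#' @importFrom utils head write.csv read.csv
NULL

# stop() with the offending argument named, call-free for clean messages
fail <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x)) {
    fail(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lo || x > hi) {
    fail(sprintf("`%s` must be in [%s, %s], got %s", name, lo, hi, x))
  }
  invisible(x)
}

check_protein_matrix <- function(x, name = "matrix", allow_missing = TRUE) {
  if (!is.matrix(x) || !is.numeric(x)) fail(sprintf("`%s` must be a numeric matrix", name))
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    fail(sprintf("`%s` must have unique sample ids as rownames", name))
  }
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    fail(sprintf("`%s` must have unique protein ids as colnames", name))
  }
  if (!allow_missing && anyNA(x)) fail(sprintf("`%s` must not contain missing values", name))
  if (any(is.infinite(x))) fail(sprintf("`%s` contains non-finite values", name))
  invisible(x)
}

check_model_matrix <- function(model, data) {
  check_protein_matrix(data, "data", allow_missing = FALSE)
  miss <- setdiff(model$proteins, colnames(data))
  if (length(miss) > 0) {
    fail("`data` lacks model proteins: ", paste(head(miss, 5), collapse = ", "))
  }
  data[, model$proteins, drop = FALSE]
}

# Deterministic per-stage seed fan-out from one user seed: stage seeds are
# derived by fixed odd-prime stepping, kept inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 104729L, preprocess = 224737L, split = 350377L,
    tune = 479909L, fit = 611953L, oof = 746773L, boruta = 882377L,
    rfe = 1020379L, epi = 1159523L, network = 1299709L
  )
  if (!stage %in% names(offsets)) fail("unknown stage: ", stage)
  as.integer((as.numeric(seed) + offsets[[stage]]) %% 2147483647)
}

# Pearson r that tolerates zero variance by returning NA with a warning
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(x, y)
}
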