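---
title: "Methods: proteomic age clocks, shadow-feature selection, and outcome analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteomic age clocks, shadow-feature selection, and outcome analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `protclock`, the
semantics of its synthetic-data generator, the reasoning behind its
numerical and algorithmic choices, and its known limitations. It is a
methods document; the README holds the quick-start worked example.

## 1. The model

### 1.1 Proteomic age and the age gap

Let $x_i \in \mathbb{R}^p$ be the normalized NPX (log-scale protein
expression) profile of sample $i$ and $a_i$ its chronological age at
blood draw. The clock is a gradient-boosted tree ensemble
$f : \mathbb{R}^p \to \mathbb{R}$ fitted to minimize squared error,

$$\hat f = \arg\min_f \sum_i \big(a_i - f(x_i)\big)^2 ,$$

yielding a *proteomic age* $\hat a_i = \hat f(x_i)$ and the central
quantity of the package, the **proteomic age gap**

$$g_i = \hat a_i - a_i .$$

A positive gap reads as "this person's proteome looks older than their
passport". The estimand behind it is a latent deviation $\delta_i$: the
generator (Section 2) writes each protein as a function of *biological
age* $a_i + \delta_i$, and the scientific claim of the approach, made by
UK Biobank proteomic aging studies such as Argentieri et al. (2024,
*Nature Medicine*), is that $g_i$ recovers $\delta_i$ well enough to
predict morbidity and mortality beyond chronological age.

Gaps reported to downstream epidemiology are always **out-of-fold**:
`oof_predict_age()` partitions the cohort into $k$ folds, fits a clock
on each complement, and predicts each sample only from the model that
never saw it. This matters because an in-sample gap is dominated by
regression residual shrinkage and its association with outcomes is
biased toward zero.

### 1.2 Fitting protocol

`fit_clock()` trains with a large estimator cap (default 5,000 trees)
and early stopping: boosting halts when holdout RMSE has not improved
for 20 consecutive rounds, and the ensemble is truncated to the best
iteration. Because the holdout age variance is fixed, minimizing RMSE
on that set is *equivalent* to maximizing holdout $R^2 = 1 -
\mathrm{SSE}/\mathrm{SST}$ — the two stopping criteria select the same
iteration. All fits are single-threaded and seeded, so every model in
the package is bit-reproducible.

`tune_clock()` does random-search hyperparameter selection by $k$-fold
CV, always scoring the package defaults as trial 1 so tuning can never
do worse than not tuning. The default trial count is deliberately small
(single digits); published biobank-scale analyses use hundreds of
trials, and the counts here are the package's own desk-scale choice,
not a statistical recommendation.

`benchmark_baselines()` fits the boosted clock alongside LASSO and
elastic-net (`glmnet`, $\lambda$ by CV) so the nonlinearity of the
boosted model can be judged against strong linear baselines on the same
splits.

### 1.3 Attribution: exact TreeSHAP in double precision

Protein importance, selection, and the interaction network all rest on
Shapley attributions $\phi_{ij}$ satisfying local additivity
$\sum_j \phi_{ij} = f(x_i) - \mathbb{E}[f]$. The package ships its own
implementation of path-dependent TreeSHAP (in C++ via Rcpp) rather than
using the booster's built-in contribution predictor, for one reason:
precision. The built-in path runs in `float32` and its additivity
residual is around $2\times10^{-6}$, too coarse to distinguish an
implementation bug from representation error. The package's engine
evaluates the parsed trees in `float64` and achieves additivity
residuals near machine epsilon ($\sim10^{-15}$), which makes exact
oracle testing possible: small models are checked against brute-force
Shapley enumeration over all feature subsets at $10^{-8}$.

One subtlety is load-bearing: xgboost stores split thresholds in
`float32`, and tree traversal compares the *float32-cast* feature value
with that threshold. The C++ evaluator reproduces the cast
(`(float)x < (float)threshold`); without it, a fraction of samples near
thresholds take the wrong branch and predictions diverge.

Pairwise interaction values use the conditioned-TreeSHAP identity
$\Phi_{ijk} = \tfrac12\big(\phi_{ij}^{(x_k \text{ present})} -
\phi_{ij}^{(x_k \text{ absent})}\big)$ symmetrized, with the diagonal
defined by row-sum reconstruction $\sum_k \Phi_{ijk} = \phi_{ij}$. Both
symmetry and reconstruction are asserted per sample at $10^{-8}$ in the
test suite.

## 2. The synthetic cohort generator

Real NPX biobank data is access-controlled, so the package carries its
own generator (`synth_config()`, `generate_cohort()`) with known ground
truth. Its semantics, and equally importantly its non-semantics:

* **Ages** are uniform on a configurable range, default 39–71 years
  (a typical recruitment window for a mid-life biobank).
* **Latent deviation** $\delta_i \sim N(0, \sigma_\delta^2)$, default
  $\sigma_\delta = 5$ years (`aging_rate_sd` scales it). Biological age
  is $b_i = a_i + \delta_i$.
* **Aging proteins** (a configurable subset) follow
  $x_{ij} = \beta_j b_i + \gamma_j (b_i - \bar a)^2 / w + \varepsilon_{ij}$,
  with slopes $\beta_j \sim N(0, \texttt{slope\_scale}^2)$ (default
  scale 0.03 NPX per year) unless an explicit `slopes` vector is given,
  a `nonlinear_fraction` of proteins receiving the quadratic term, and
  $\varepsilon_{ij} \sim N(0, \texttt{noise\_sd}^2)$. Null proteins are
  pure noise.
* **Missingness** is MCAR at rate `missing_rate` (default 5%), with a
  configurable fraction flagged as below detection limit. There is no
  informative missingness mechanism.
* **Covariates** (sex, deprivation, recruitment center, activity,
  smoking, BMI around 27, prevalent hypertension) are drawn
  independently of $\delta$; they exist to exercise adjustment code,
  not to encode confounding.
* **Outcomes** (`simulate_survival()`) are exponential given the linear
  predictor: constant baseline hazard $\lambda_0$, hazard
  $\lambda_i = \lambda_0 e^{\gamma \delta_i}$, administrative censoring
  at the horizon. `baseline_hazard_for_rate()` inverts the marginal
  event probability over the $\delta$ distribution by quadrature to hit
  a target event rate.

What the generator deliberately does **not** emulate: plate and batch
effects, assay drift, informative/limit-of-detection-censored
missingness beyond a flag, correlated protein modules (beyond the
shared dependence on $b_i$), non-proportional hazards, competing risks,
and confounded covariates. Tests that rely on those absences say so.

## 3. Preprocessing

`preprocess_cohort()` reproduces a standard NPX pipeline: proteins
missing in **strictly more than 10%** of samples are excluded (a
protein at exactly 10% survives; drops are logged with the offending
fraction), cohorts are intersected to a common protein set, remaining
gaps are imputed, and proteins are min–max scaled then median-centered.
Normalization parameters are fitted on a configurable subset
(`fit_subset`): the pipeline default fits on the training split only,
which is the leakage-safe choice; passing `NULL` fits on the full
cohort, matching the common published practice.

Imputation (`impute_proteins(method = "chained")`) is iterative
regression imputation: median initialization, then repeated passes in
which each incomplete protein is regressed on its most-correlated
complete-enough peers and missing cells are replaced by regression
means, until convergence or five rounds. This is a deterministic
stand-in for chained-equation imputation with donor matching
(PMM-style); it preserves conditional means but **understates
imputation variance**, which is acceptable here because imputed values
only feed a tree ensemble, not a variance estimate. Observed cells are
never modified, and the tests assert it cell-by-cell.

## 4. Feature selection

### 4.1 Boruta with shadow features

`boruta_select()` pairs every surviving protein with a *shadow*: an
independent permutation of its own column, i.e. noise with the same
marginal. Per trial, a boosted model is fitted on real-plus-shadow
columns and each column's mean $|\phi|$ importance is computed; a
protein survives an iteration only if its trial-averaged importance
exceeds the trial-averaged shadow reference (at the default
`threshold = 1`, the maximum shadow importance). Failures are dropped
and the loop repeats until an iteration drops nothing.

Two design points control the false-positive rate, and both were
adopted after observing failures without them:

* **Shadow-pool floor.** With few survivors the max over their own
  shadows is a weak null, so the pool is padded to at least five shadow
  columns (classic Boruta's minimum).
* **Early-stopped trial fits.** By default each trial trains with the
  estimator cap plus early stopping against an internal 85:15 holdout,
  rather than a fixed round count. On signal-free data early stopping
  halts almost immediately, so no feature can accumulate importance
  over its shadows; with fixed round counts, the one or two proteins
  with the strongest *spurious* age correlation survive the first
  iteration (a winner's-curse selection) and then face only their own
  shadows, yielding persistent false positives. A fixed `nrounds` path
  remains available for speed where false-positive control is not the
  concern.

### 4.2 SHAP-guided recursive elimination

`shap_rfe()` walks a selected panel down to five proteins, one per
step. Each step fits $k$ cross-validated models, records mean CV
Pearson $r$ and $R^2$, and removes one protein by a deterministic vote:
the per-fold least-important protein when folds are unanimous,
otherwise the protein ranked last in the most folds, with residual ties
broken lexicographically by protein id. The lexicographic tie-break is
arbitrary but total, which is what determinism requires.
`select_reduced_panel()` then returns the smallest panel retaining a
target fraction (default 95%) of the full panel's metric.

## 5. Epidemiology

* **Association scans** (`associate_gap()`) regress each phenotype on
  the gap with covariate adjustment (linear or logistic by phenotype
  type) and correct the scan with Benjamini–Hochberg. `bh_fdr()` wraps
  the standard step-up procedure; the suite verifies it against a
  from-scratch implementation of the step-up definition on a thousand
  random vectors.
* **Cox models** (`cox_hazard()`) fit the gap against incident events
  with Efron tie handling, excluding prevalent cases, at three
  adjustment tiers (age/sex; plus deprivation, center, lifestyle; plus
  BMI and hypertension). Results carry Wald CIs, a `low_power` flag
  below an event floor, and BH-adjusted p-values across endpoints.
  A note on validation: the suite's hazard-recovery checks feed the
  *latent* deviation as exposure. The estimated gap is a noisy proxy of
  $\delta$, and classical measurement-error attenuation biases its
  log-HR toward zero by roughly the reliability ratio, so a tight
  recovery tolerance is only meaningful in the noiseless-exposure
  limit; using $\delta$ tests the survival machinery rather than the
  clock.
* **Kaplan–Meier incidence** (`km_incidence_by_decile()`) computes
  product-limit cumulative incidence $1 - \hat S(t)$ per gap decile.
  The `age` column is a *plotting convention*: group mean recruitment
  age plus follow-up time. Estimation happens on follow-up time;
  re-estimating on an age timescale with delayed entry would be a
  different (also defensible) analysis.
* **`fold_risk(hr, delta_years)`** is the compounding identity
  $\mathrm{HR}^{\Delta}$: a per-gap-year hazard ratio raised to a
  years-of-gap contrast.
* **`multimorbidity_gap()`** compares mean gaps across disease-count
  strata (counts of four and above pooled), with normal-theory CIs and
  optional age stratification.

## 6. Networks

`shap_interaction_matrix()` feeds `interaction_network()`: edges are
protein pairs whose mean $|\Phi_{jk}|$ exceeds a threshold, optionally
filtered to pairs present in an external reference edge list
(coexpression scores, kept at strictly $> 0.7$) with cascade pruning of
nodes left isolated. `network_overlap()` reports Jaccard agreement
between networks.

## 7. Numerical and engineering choices

* Double-precision tree evaluation with `float32` split casts
  (Section 1.3); attribution tolerances $10^{-6}$ (additivity on
  realistic models) and $10^{-8}$ (brute-force equivalence, symmetry,
  reconstruction) chosen an order of magnitude above observed residuals
  but far below `float32` noise.
* All stochastic steps take explicit seeds, derived per purpose with a
  string-salted generator so sub-procedures do not share streams.
* `config_hash()` is a hand-rolled 32-bit FNV-1a over the canonical
  JSON serialization of the configuration, implemented with 16-bit-half
  modular arithmetic in doubles because R's bitwise integer operations
  overflow at $2^{31}$.
* The pipeline (`run_pipeline()`) writes text-only artifacts (CSV,
  JSON) with paths serialized relative to the output directory, so
  identical configurations yield byte-identical bundles regardless of
  where they run — asserted end to end in the suite.
* Test problem sizes (cohorts of hundreds to a few thousand, panels of
  tens to hundreds) are the package's choice to keep a laptop-scale
  suite; they are not statements about required sample sizes.

## 8. Limitations

* The generator's protein model is linear-plus-quadratic in biological
  age with independent noise; real proteomes have correlated modules,
  batch structure, and informative missingness the package does not
  simulate, so absolute performance numbers on synthetic cohorts do not
  transfer.
* The clock engine is xgboost; published clocks often use other
  gradient-boosting implementations, and tree-level details (growth
  policy, regularization defaults) differ even at equal accuracy.
* Chained imputation understates uncertainty (Section 3); do not reuse
  imputed matrices for variance-sensitive inference.
* Cox models assume proportional hazards and exponential-style
  censoring as simulated; no competing-risk machinery is provided.
* The measurement-error attenuation of gap-based hazard ratios
  (Section 5) applies to real analyses too: a reported HR per gap year
  is a lower bound on the HR per latent-deviation year.
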