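# protclock

Proteomic age clocks in R: gradient-boosted age prediction from NPX-scale
protein panels, shadow-feature selection, exact double-precision TreeSHAP
attribution, and the downstream epidemiology of the proteomic age gap.

## The scientific problem

Blood proteomes drift with age in a way that is partly decoupled from the
calendar. A *proteomic age clock* exploits this: train a model to predict
chronological age from circulating protein levels, and read the residual —
the **proteomic age gap**, predicted minus chronological age — as a marker
of accelerated or decelerated biological aging. In large biobank studies
(e.g. Argentieri et al., 2024, *Nature Medicine*), people whose proteomes
look years older than their passports go on to develop chronic disease and
die earlier, even after adjusting for the usual risk factors.

`protclock` implements that full analysis arc on synthetic cohorts with
known ground truth, so every stage is testable without access-controlled
biobank data:

1. **Simulate** multi-cohort NPX data with planted age signal, a latent
   aging deviation per person, MCAR missingness, covariates, and
   exponential survival outcomes tied to the deviation.
2. **Preprocess** — exclude proteins missing in >10% of samples, intersect
   cohorts, impute by chained regression, min–max scale and median-center.
3. **Train the clock** — xgboost with a 5,000-tree cap and 20-round early
   stopping; out-of-fold prediction so gaps are never in-sample; LASSO and
   elastic-net baselines.
4. **Select proteins** — iterative Boruta against permuted shadow features
   scored by Shapley importance, then SHAP-guided recursive elimination to
   a compact panel.
5. **Epidemiology** — Benjamini–Hochberg–corrected association scans,
   tiered Cox proportional-hazards models with prevalent-case exclusion,
   Kaplan–Meier cumulative incidence by gap decile, multimorbidity trends,
   and fold-risk compounding.
6. **Networks** — protein–protein interaction graphs from exact SHAP
   interaction values, with external coexpression filtering.

## The model

For protein profile $x_i \in \mathbb{R}^p$ and age $a_i$, the clock is a
boosted tree ensemble $\hat f$ minimizing $\sum_i (a_i - f(x_i))^2$, the
proteomic age is $\hat a_i = \hat f(x_i)$, and the gap is

$$g_i = \hat a_i - a_i,$$

an estimate of the latent deviation $\delta_i$ in the generative model
$x_{ij} = \beta_j (a_i + \delta_i) + \dots + \varepsilon_{ij}$. Hazards of
incident disease are modeled as $\lambda_i = \lambda_0(t)\, e^{\gamma g_i}$
(Cox, Efron ties), so a hazard ratio $e^{\gamma}$ per gap year compounds
to $e^{\gamma \Delta}$ over a $\Delta$-year gap contrast (`fold_risk()`).

Attributions are exact path-dependent TreeSHAP computed in double
precision by the package's own Rcpp engine (local additivity to ~1e-15;
verified against brute-force Shapley enumeration in the tests), including
pairwise interaction values.

## Worked example

```r
library(protclock)

## 1. Simulate a cohort with known ground truth
cfg <- synth_config(n_samples = 1500, n_proteins = 100, n_aging = 20,
                    noise_sd = 0.3, aging_rate_sd = 2, seed = 42)
cohort <- generate_cohort(cfg)
dim(cohort$proteins)
#> [1] 1500  100

## 2. Preprocess: missingness filter, imputation, normalization
prep <- preprocess_cohort(cohort$proteins)
X <- prep$matrix
age <- setNames(cohort$phenotypes$age, cohort$phenotypes$sample_id)

## 3. Train a clock with early stopping on a held-out split
sp <- split_cohort(rownames(X), 0.70, seed = 1)
inner <- split_cohort(sp$train, 0.85, seed = 2)
model <- fit_clock(X[inner$train, ], age[inner$train],
                   clock_hyperparams(seed = 1),
                   X[inner$test, ], age[inner$test])
evaluate_predictions(predict(model, X[sp$test, ]), age[sp$test])
#> $pearson_r
#> [1] 0.9469288
#>
#> $r_squared
#> [1] 0.8961663
#>
#> $rmse
#> [1] 2.886271
#>
#> $mae
#> [1] 2.236777

## 4. Out-of-fold age gaps and the extreme-band contrast
gap <- oof_predict_age(X, age, clock_hyperparams(seed = 1), k = 5, seed = 3)
s <- summarize_gap(gap, tail_fraction = 0.05)
s$bands
#>        band  n  mean_gap
#> 1 bottom_5% 75 -6.006621
#> 2    top_5% 75  6.093747
s$top_bottom_difference
#> [1] 12.10037

## 5. Compound a per-gap-year hazard ratio over a gap contrast
fold_risk(hr = 1.10, delta_years = 6.3)
#> [1] 1.822946
```

Even on this small synthetic cohort the clock tracks age at r ≈ 0.95, and
the people in the top 5% of the out-of-fold gap distribution look about
12 years "older" than those in the bottom 5%. A hazard ratio of 1.10 per
gap year compounds to roughly a 1.8-fold risk over a 6.3-year gap
contrast.

The whole arc can also be run as one reproducible, config-driven pipeline:

```r
cfg <- pipeline_config(seed = 7)           # or read_pipeline_config("cfg.yaml")
bundle <- run_pipeline(cfg, "out_dir")     # text-only artifacts + bundle.json
write_report(bundle, "out_dir/report.txt") # byte-identical on re-runs
```

Methodological details — generator semantics and limitations, the
early-stopping and Boruta design decisions, numerical tolerances — are in
`vignettes/proteomic-age-clock-methods.Rmd`.

## Package layout

- `R/synthdata.R` — cohort generator with ground truth and survival outcomes
- `R/preprocess.R` — filtering, imputation, normalization
- `R/clock.R` — fitting, tuning, out-of-fold gaps, baselines, save/load
- `R/treeshap.R`, `src/treeshap.cpp` — exact double-precision TreeSHAP
- `R/featselect.R` — Boruta shadow selection, SHAP-RFE, panel reduction
- `R/epi.R` — BH, association scans, Cox tiers, KM, fold risk, multimorbidity
- `R/network.R` — SHAP-interaction networks and overlap
- `R/pipeline.R` — config, staged runner, deterministic bundles and reports
- `tests/testthat/` — module tests plus an acceptance suite with
  independent oracles (brute-force Shapley, step-up BH, hand product-limit KM)

## License

MIT (see `LICENSE`).
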