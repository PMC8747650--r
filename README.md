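# rooibosclass

Rooibos (*Aspalathus linearis*) herbal tea is marketed either fermented
(oxidised; FR) or unfermented ("green"; UFR), and the two product types
differ in phenolic composition and antioxidant capacity. A natural
quality-control question is whether a handful of cheap spectrophotometric
assays — total phenolic content (TPC, gallic-acid equivalents), Trolox
equivalent antioxidant capacity (TEAC) and ferric-reducing antioxidant
power (FRAP), each measured in water and in methanol extracts — suffices to
tell FR from UFR, and whether machine-learning classifiers add anything
over plain multivariate statistics on such a small tabular dataset
(~50 samples per class, at most 6 features).

`rooibosclass` implements that benchmarking study end to end for R users
working with small assay panels:

- **Statistical baseline.** A per-class Gaussian fit (maximum-likelihood
  mean, sample covariance) classifying a point `x` to the class `c` with
  the smaller multivariate Z-score, i.e. the minimum Mahalanobis distance

  `D_c(x) = sqrt((x - mu_c)' Sigma_c^{-1} (x - mu_c))`,

  with automatic ridge escalation for near-singular covariances and an
  optional full log-likelihood variant (`gaussian_baseline()`).
- **ML arms.** Logistic regression (glmnet), SVM (e1071), random forest
  (randomForest) and kNN under a uniform contract: exhaustive grid search
  selected by stratified 3-fold cross-validated accuracy on the training
  half (`train_arm()`).
- **Evaluation and uncertainty.** Accuracy = (TP+TN)/(TP+TN+FP+FN) on a
  stratified half/half split, single-assay ROC/AUC sweeps, and a
  leave-one-out jackknife that re-optimises every classifier on each
  reduced dataset, yielding error bars
  `±2 · sqrt((n-1)/n · Σ(θ_i − θ̄)²)` on the ML-minus-baseline accuracy
  difference (`jackknife_compare()`, `run_full_comparison()`).
- **Synthetic data.** A multivariate Gaussian generator whose defaults are
  parameterised from the published per-class summary tables (means,
  range-derived SDs, signed-squared within-solvent correlations, zero
  cross-solvent correlation, 51 FR / 47 UFR), so the whole pipeline is
  testable although the raw measurements are available only on request
  (`default_gen_params()`, `generate_assay_data()`).
- **Descriptives.** Per-group summary tables, pairwise Pearson
  correlations with classical standard errors, and 95% confidence ellipses
  with a chi-squared(2 df) threshold (`summarize_assays()`,
  `correlation_table()`, `confidence_ellipse()`).

## Worked example

```r
library(rooibosclass)

d <- generate_assay_data(default_gen_params(seed = 1))
table(d$label)
#>  FR UFR
#>  51  47

assay_roc(d, "TEAC", "water")
#> ROC TEAC / water: AUC = 0.5970 (lower-is-UFR)
assay_roc(d, "TEAC", "methanol")
#> ROC TEAC / methanol: AUC = 0.8836 (higher-is-UFR)

spec <- feature_set(c("TPC", "TEAC"), "methanol")
f <- extract_features(d, spec)
gaussian_baseline(f$x, f$labels, spec = spec)
#> Gaussian minimum-Mahalanobis baseline (2 features, rule = mahalanobis)
#>   FR  n = 51, mean = (258.1, 1989)
#>   UFR n = 47, mean = (303.4, 2368)
#>   ridge applied: 0

jackknife_compare(d, spec, "RF", split_config(seed = 1),
                  grids = list(RF = list(ntree = 100, max_depth = Inf)))
#> RF vs baseline on {TPC,TEAC}/methanol: diff = -0.0308 +/- 1.1416 (not significant)
```

The ROC curves say that a single methanol-extract TEAC threshold already
separates the classes well (AUC 0.88) while the same assay in water is
near-useless (AUC 0.60); the jackknife comparison says the random forest
is, if anything, slightly worse than the two-feature Gaussian baseline and
that the difference is far from significant — the study's headline
pattern. `run_full_comparison()` repeats this over all 21 feature sets
(7 assay subsets × 3 solvent scopes) and all 4 ML methods; with the
default 98-sample dataset that schedule contains
`count_scheduled_optimizations(98, 21, 4)` = 8232 separate grid-search
optimisations.

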