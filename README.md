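# tabaug

When does augmenting a small tabular clinical dataset with *synthetic*
records actually improve a prognostic model? `tabaug` is an R framework for
studying that question end to end. It is aimed at biostatisticians and
machine-learning methodologists working with mixed-type health data
(numeric and categorical predictors, a binary outcome, prevalence-driven
imbalance) who want to quantify — rather than assume — the value of
generative-model data augmentation.

## What it does

Given a base dataset of size *n₀*, a generative model fitted **on that base
only** produces *n′* synthetic records; the workload model is trained on
the augmented dataset of size *n = n₀ + n′* and scored by ROC-AUC on
held-out data. Around this core, the package provides:

* **Schema-typed data handling** — CSV + YAML-sidecar I/O, declared level
  universes, outcome-stratified splitting, leakage-safe target encoding of
  high-cardinality categoricals.
* **Synthetic populations** — a latent Gaussian copula simulator with
  tunable size, mixed predictor types, level imbalance (Zipf), outcome
  prevalence and predictor–outcome signal, plus `"simple"` / `"complex"`
  presets spanning baseline ROC-AUC regimes.
* **Generators** — bootstrap resampling, sequential decision trees (CART
  chained over the variable order, sampling from leaf pools), Bayesian
  networks (hill-climb BIC structure search, Dirichlet-smoothed CPTs,
  ancestral sampling), and an adapter contract for external synthesizers.
* **Complexity characteristics** — the eight covariates of the benefit
  model: *n₀*, predictor degrees of freedom (1 per numeric, *k − 1* per
  categorical), imbalance factor `max(p/(1−p), (1−p)/p)`, mean standardized
  entropy, the coefficient of variation of pairwise mutual information,
  Gower-distance class separability (mean intraclass NN distance over mean
  interclass NN distance), baseline ROC-AUC, and predictor count.
* **Diversity metric** — an extended isolation forest (random-hyperplane
  splits) trained on the base scores both datasets; with contamination
  rates `r_j = P(score ≥ τ_j)` on the grid τ = 0.01, …, 1.00 and
  `x_j = r_j(augmented) − r_j(base)`,

  ```
  diversity = (1/100) Σ_j 1(x_j ≥ 0) · x_j (2 − x_j)
  ```

* **Simulation engines** — part 1: the n₀ grid (40 sizes, 20–50,000) ×
  10 geometric series × 30 sizes `n′ = [b^(i+4)]`, `b ~ N(1.5, 0.005)`,
  all evaluated against one fixed test partition; part 2: a nested
  5-fold cross-validation case study selecting the generator and `n′_max`
  that maximize fold-averaged ROC-AUC, with a bootstrap-resampling control
  at the same size and one-tailed **exact sign-flip permutation tests**
  across datasets.
* **Benefit model** — a random-intercept logistic GLMM
  (`benefit ~ characteristics + (1 | dataset)`) over the per-
  {dataset, n₀, generator} benefit indicator, reported unstandardized and
  standardized with odds ratios and Wald 95% CIs.

## Worked example

```r
library(tabaug)

pop <- generate_population(preset_population("complex", n_rows = 12000, seed = 11))
sp  <- split_population(pop, 0.7, seed = 1)
ws  <- workload_settings(tuning_budget = 3, inner_folds = 3, nrounds = 50, seed = 1)

base <- draw_base(sp$train, 100, seed = 103)          # n0 = 100
baseline <- evaluate_auc(train_workload(base, ws), sp$test)

gen <- fit_seq_trees(base)
aug <- augment(base, gen, 2000, seed = 2021)          # n = 100 + 2000
augmented <- evaluate_auc(train_workload(aug, ws), sp$test)

c(baseline = baseline, augmented = augmented)
#>  baseline augmented
#> 0.5613800 0.6212383

relative_improvement(baseline, augmented)
#> [1] 10.66

dataset_diversity(base, aug, n_trees = 100, seed = 4)
#> <tabaug_diversity> 0.0036 (positive at 9/100 thresholds)
```

Here a 100-record base from the high-cardinality preset gains about 0.06
ROC-AUC from sequential-tree augmentation, and the augmented data carries
more outlying structure than the base — the mechanism the framework is
built to measure. Gains vary across base draws (augmentation sometimes
hurts); the acceptance script below measures how often it helps over
repeated draws rather than relying on any single one. The three
across-dataset comparisons are one call on any case-study table:

```r
tests <- case_study_tests(case_study_reference())
tests$augmented_vs_baseline$p_value   # 1/128  = 0.0078
tests$augmented_vs_resampled$p_value  # 2/128  = 0.016
```

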