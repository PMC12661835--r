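---
title: "Evaluating synthetic-data augmentation: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating synthetic-data augmentation: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tabaug` studies a simple question with many moving parts: given a small
mixed-type clinical dataset, does concatenating synthetic records to it
before training improve out-of-sample discrimination of a prognostic
model? This vignette explains the statistical machinery, the defaults, and
the choices we made where the design was genuinely open.

## The augmentation protocol

A base dataset of size $n_0$ is drawn from a training partition by
outcome-stratified sampling without replacement. A generative model is
fitted on the base **only**, and $n'$ synthetic records are drawn from it;
the workload trains on the augmented dataset of size $n = n_0 + n'$ and is
scored by ROC-AUC on data the generator never saw. Synthetic-data sizes
follow a geometric ladder $n' = [\,b^{\,i+4}\,]$, $i = 1,\dots,30$, with
$b \sim N(1.5,\ 0.005)$, which concentrates evaluation at small $n'$ where
behaviour changes fastest. We draw one $b$ per series (ten series per
$n_0$), making each series internally coherent; a per-element draw is
available as a switch (`per_element_b`) since the alternative reading is
defensible. Rounding is half-away-from-zero.

In the population-scale grid (part 1) the population is split 70/30 once
and the same test partition scores every cell, so differences between
cells are not confounded by test-set variation. In the case-study engine
(part 2) no large population exists, so a nested 5-fold cross-validation
is used instead: generators are fitted separately inside each outer
training partition (never on the evaluation fold), the workload's
hyperparameter tuning runs in an inner CV, the final ROC-AUC per
(generator, $n'$) is the mean over the five outer folds, and the pair
maximizing that mean defines the selected generator and $n'_{max}$. On
ties we take the smallest $n'$ — the cheapest model that achieves the
maximum. The baseline is the fold-averaged ROC-AUC of the un-augmented
training partitions.

## The workload

The workload is a gradient-boosted decision-tree classifier (xgboost,
histogram method). Categorical predictors are target-encoded: level $\ell$
maps to the smoothed positive rate
$(n_\ell \bar y_\ell + s\,\bar y)/(n_\ell + s)$ with smoothing $s = 10$
(levels with little evidence shrink to the global rate); encodings are
always fitted on training rows only, and unseen levels fall back to the
global rate. Hyperparameters are tuned by seeded random search over
conventional ranges — learning rate $[0.01, 0.3]$ (log), depth $[3, 12]$,
minimum child size $[5, 50]$ records, row/feature subsampling
$[0.6, 1]$, L1/L2 $[10^{-8}, 10]$ (log) — scored by mean ROC-AUC over an
outcome-stratified inner CV. The minimum child size is tuned as a record
count and translated to xgboost's hessian-weight units with the logistic
bound of $0.25$ per record; without that translation, bases of a hundred
records cannot support any split and the baseline degenerates to 0.5.
Random search was chosen as the tuner because it is transparent, trivially
seeded, and at 30 candidates explores these low-dimensional spaces
adequately; the trial budget, not the search strategy, is the binding
resource at this problem size. Tests and the acceptance script use reduced
budgets (3 candidates, 3 folds, 40–60 rounds) — stated here as the
package's own scaling choice for its built-in examples.

ROC-AUC is computed rank-based with ties counting one half, i.e. the
Mann–Whitney $U$ statistic divided by $n_+ n_-$; the test suite verifies
that identity against `wilcox.test` on random instances.

## Generators

**Bootstrap** resamples whole base rows with replacement. It is the
control: it adds sample size but, by construction, no new records.

**Sequential decision trees** synthesize variables one at a time in schema
order (configurable): the first variable from its empirical marginal, each
later variable from a CART tree (rpart, `cp = 0`, `minbucket = 5`,
`maxdepth = 12`) on the variables already synthesized. A synthetic row
walks its prefix down the tree and draws from the reached leaf — class
frequencies for categoricals, a uniform draw from the leaf's pool of
observed values for numerics — so cells never leave the observed support
and we avoid inventing a smoothing kernel. One engine-level caveat: for
responses with more than two classes, rpart's split search over a
categorical predictor enumerates level subsets exhaustively, which is
exponential in the level count; predictors with more than 10 observed
levels are therefore frequency-rank encoded for split search only (leaf
pools stay on raw values). With quantile-sliced or frequency-ordered
levels this loses little structure and keeps fitting linear in the level
count.

**Bayesian networks** first discretize numerics into 5 equal-frequency
bins, then learn a DAG by greedy hill climbing from the empty graph over
add/remove/reverse arc moves maximizing the decomposable BIC
$\sum_v \big[\log L_v - \tfrac{1}{2}\log(n)\, q_v (r_v - 1)\big]$, with at
most 3 parents per node. Conditional probability tables use additive
Dirichlet smoothing with pseudo-count 1 over the observed level universe —
a posterior-mean style estimate; the literal MAP mode with a flat prior
reduces to the MLE and produces zero cells for unseen parent
configurations, which breaks ancestral sampling. Sampling proceeds in
topological order; numeric bins are back-transformed by a uniform draw
within the bin's edges.

External deep synthesizers (CTGAN/TVAE-class models) are integrated
through an adapter contract only — a command invoked as
`cmd train.csv schema.yaml m seed out.csv` returning schema-conformant
CSV. Their internals are out of scope here.

All generators guarantee: exactly $m$ rows per call, determinism given the
seed, and sampled categorical levels restricted to levels observed in the
training data.

## The eight complexity characteristics

The benefit model uses: base size $n_0$; degrees of freedom (1 per
numeric, $k-1$ per categorical predictor); imbalance factor
$\max\{p/(1-p),\ (1-p)/p\}$; mean standardized entropy $H_j / \log k_j$
averaged over predictors (numerics binned into 10 equal-frequency bins; a
constant predictor contributes 0 by the convention $H/\log 1 \equiv 0$);
the coefficient of variation (sample SD over mean) of plug-in mutual
information across all unordered predictor pairs, natural log, with a
warning-and-zero guard when the mean MI is zero; Gower-distance class
separability; baseline ROC-AUC; and the predictor count.

Separability averages, over records, the Gower distance to the nearest
same-class neighbour and divides by the average distance to the nearest
other-class neighbour. We aggregate as a ratio of means rather than a mean
of per-record ratios: duplicate records make individual ratios 0/0-prone,
while the ratio of means is defined whenever any interclass distance is
positive (an error is raised in the degenerate all-duplicates case). The
10-bin discretization grain and the aggregation are configuration, not
ground truth — the relevant precedents do not pin them down. The distance
matrix is $O(n^2)$; profiles of bases beyond 2000 rows use a seeded
stratified subsample.

## The diversity metric

A record is "diverse" to the extent it is an outlier relative to the base.
An extended isolation forest — isolation trees with random oblique
hyperplane splits, 200 trees, subsample $\psi = \min(256, n)$, depth limit
$\lceil \log_2 \psi \rceil$ — is trained on the base; scores use
$s = 2^{-E[h]/c(\psi)}$ so they live in $(0,1)$ and the fixed threshold
grid $\tau_j = 0.01, \dots, 1.00$ is meaningful. Records are encoded
outcome-free before the forest: categorical levels map to their training
frequency and numerics are min-max scaled — target-style encoding here
would leak the outcome into a metric that is supposed to measure record
novelty. With contamination rates $r_j = \Pr(s \ge \tau_j)$ computed on
the full base and full augmented dataset and $x_j$ their difference,

$$\mathrm{diversity} = \frac{1}{100} \sum_{j=1}^{100}
  \mathbf{1}(x_j \ge 0)\; x_j\,(2 - x_j).$$

The weight $x(2-x)$ is increasing on $[0,1]$, negative differences
contribute nothing, and the score is 0 exactly when the augmented data adds
no outlying structure — bootstrap augmentation sits near 0 by design.

## Permutation tests and the benefit model

Across case-study datasets, paired comparisons (augmented vs baseline
ROC-AUC, augmented vs resampled ROC-AUC, generative vs resampled
diversity) use a one-tailed exact sign-flip test: all $2^n$ assignments of
signs to the absolute differences are enumerated and the p-value is the
fraction of assignments whose mean is at least the observed mean, ties
counting as extreme (with seven datasets and all differences positive this
gives exactly $1/128 = 0.0078$). Beyond 20 pairs the test switches to a
seeded Monte-Carlo approximation and says so.

The benefit indicator is 1 for a {dataset, $n_0$, generator} combination
when augmentation beat that combination's baseline. "Beat" is ambiguous
when 300 runs per combination exist; the default takes the best
series-averaged ROC-AUC across the 30 $n'$ levels — averaging first damps
Monte-Carlo noise, maximizing after reflects that the protocol gets to
choose $n'$. `any_run` and `overall_mean` are available alternatives. The
model is a logistic GLMM with a random intercept per dataset, estimated by
Laplace approximation via `lme4::glmer` (the module owns the table
construction, standardization, odds ratios and Wald 95% CIs; lme4 is the
estimation engine). Estimates are reported raw and with covariates
standardized to unit SD; standardization changes scales, not Wald
z-statistics, so the p-value ordering is identical — the suite checks this
numerically.

## The synthetic population simulator

No real populations ship with the package, so every end-to-end property is
exercised on simulated ones. A latent multivariate Gaussian with
exchangeable correlation $\rho$ (default 0.25–0.3) drives everything:
numeric predictors are latent coordinates; categorical predictors slice
their coordinate at quantile boundaries into $k$ levels, equal-probability
or Zipf-weighted ($p_r \propto 1/r$) for the administrative-data presets;
the outcome is Bernoulli with logit linear in the latent coordinates plus
noise, the intercept calibrated by bisection to hit a target prevalence
(tolerance $10^{-3}$ in expectation). Two presets bracket the complexity
range: `"simple"` (6 predictors, max cardinality 5, prevalence 0.3) and
`"complex"` (7 predictors including 50- and 100-level Zipf categoricals,
prevalence 0.15). Effect sizes were set so large-sample baseline ROC-AUC
lands near 0.75 (simple) and 0.70 (complex) — mid-range prognostic
performance.

What the simulator does **not** emulate: real missing-data mechanisms,
deterministic clinical constraints between variables, longitudinal
structure, non-monotone predictor–outcome relationships, and label noise
correlated with predictors. Tests passing on these populations show the
machinery is correct and the mechanism (generative augmentation adds
diversity and lifts small-$n_0$ ROC-AUC) is reproducible under controlled
conditions; they do not certify effect sizes on any real dataset.

## Numerical conventions and degenerate inputs

Seeds: every stochastic operation takes an explicit seed; composite stages
derive recorded sub-seeds. Missing predictor cells: an explicit
`"(missing)"` level for categoricals, `NA` passed through to the workload
for numerics (xgboost handles them natively); rows with missing outcome
are dropped at load. Zero-range numerics contribute 0 to Gower distances;
constant predictors contribute 0 entropy; a zero-variance covariate is
dropped from standardization with a warning; a fold or cell that loses an
outcome class is recorded as failed rather than silently dropped.
Contamination-curve thresholds compare with a $10^{-12}$ slack so exact
grid values are not lost to floating point, and the sign-flip test uses a
relative $10^{-9}$ tie tolerance.

## Problem sizes in the built-in runs

The packaged tests and the acceptance script run the full pipeline at
reduced scale: populations of 4,000–12,000 rows, bases of 100 records,
$n' \in \{500, 2000\}$, 3-candidate tuning, 10 mechanism replicates and 20
diversity seeds, and a 100-replicate parameter-recovery study for the
GLMM (2,000 observations, 20 clusters). These sizes were chosen so each
stochastic assertion has a defensible error bound — binomial checks use
3-standard-error bands at their stated n, and the 15-of-20 sign-test
threshold is the 0.05-level one-sided critical value — while the whole
suite stays comfortably interactive. The full-scale design — 40
$n_0$ values × 10 series × 30 sizes, 12,000 augmented datasets per
population — is expressed in configuration and verified by counting, and
`run_part1()` will execute it unchanged given the time.

## Known limitations

Structure learning is greedy hill climbing without restarts or tabu moves;
on small bases the learned DAG is often sparse. The sequential-tree
generator inherits rpart's axis-aligned splits and does not model residual
dependence within leaves beyond the pooled values. The diversity forest's
settings (200 trees, $\psi = 256$) follow isolation-forest conventions
rather than any problem-specific calibration. The benefit GLMM assumes a
linear logit in the characteristics; the grid results themselves suggest
the $n_0$ effect is non-linear, which is one reason $n_0$ can appear
non-significant in such models.
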