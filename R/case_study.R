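# Case-study engine: leakage-safe nested 5-fold cross-validation, selection
# of the synthetic-data size maximizing fold-averaged ROC-AUC, a bootstrap
# resampling comparison at that size, and exact paired permutation tests.

#' Default geometric ladder of synthetic-data sizes
#'
#' `round(1.5^(i+4))` for `i = 1..30`, spanning roughly 8 to 1e6 records.
#'
#' @param length_out Number of ladder steps (default 30).
#' @return Integer vector.
#' @export
default_n_prime_grid <- function(length_out = 30L) {
  as.integer(round_half_away(1.5^(seq_len(length_out) + 4)))
}

#' Exact paired permutation test (one-tailed, greater)
#'
#' Enumerates all `2^n` assignments of signs to the absolute paired
#' differences; the p-value is the proportion of assignments whose mean is
#' at least the observed mean (ties count as extreme). Above `n_max_exact`
#' pairs a seeded Monte-Carlo sign-flip approximation is used and flagged.
#'
#' @param differences Numeric vector of paired differences.
#' @param n_max_exact Largest n enumerated exactly (default 20).
#' @param n_mc Monte-Carlo draws beyond that (default 20000).
#' @param seed Seed for the Monte-Carlo branch.
#' @return An object of class `tabaug_permtest`: list with
#'   `observed_mean_difference`, `p_value`, `n_pairs`, `n_enumerated`,
#'   `exact`.
#' @export
exact_paired_permutation_test <- function(differences, n_max_exact = 20L,
                                          n_mc = 20000L, seed = 1L) {
  d <- as.numeric(differences)
  if (!length(d)) stop("no differences supplied")
  n <- length(d)
  obs <- sum(d)
  absd <- abs(d)
  tol <- 1e-9 * max(1, max(absd))
  if (n <= n_max_exact) {
    sums <- 0
    for (a in absd) sums <- c(sums + a, sums - a)
    p <- mean(sums >= obs - tol)
    n_enum <- 2^n
    exact <- TRUE
  } else {
    local_rng(seed)
    signs <- matrix(sample(c(-1, 1), n * n_mc, replace = TRUE), nrow = n_mc)
    sums <- drop(signs %*% absd)
    p <- mean(sums >= obs - tol)
    n_enum <- n_mc
    exact <- FALSE
  }
  structure(list(observed_mean_difference = mean(d), p_value = p,
                 n_pairs = n, n_enumerated = n_enum, exact = exact),
            class = "tabaug_permtest")
}

#' @export
print.tabaug_permtest <- function(x, ...) {
  cat(sprintf(
    "<tabaug_permtest> mean diff %.4f, one-tailed p = %.4g (%s, %d pairs)\n",
    x$observed_mean_difference, x$p_value,
    if (x$exact) sprintf("exact, %d assignments", x$n_enumerated)
    else sprintf("Monte-Carlo, %d draws", x$n_enumerated), x$n_pairs))
  invisible(x)
}

#' Relative ROC-AUC improvement in percent
#'
#' @param baseline Baseline ROC-AUC (> 0).
#' @param augmented Augmented ROC-AUC.
#' @return `(augmented - baseline) / baseline * 100`.
#' @export
relative_improvement <- function(baseline, augmented) {
  if (any(baseline <= 0)) stop("baseline ROC-AUC must be positive")
  (augmented - baseline) / baseline * 100
}

# Stratified outer folds as a list of row-index vectors (test rows per fold).
outer_folds <- function(y, k, seed) {
  local_rng(seed)
  fold <- stratified_folds(y, k)
  lapply(seq_len(k), function(f) which(fold == f))
}

#' Nested cross-validated augmentation evaluation of one dataset
#'
#' Outcome-stratified outer folds; within each outer fold, every generator
#' is fitted on the training partition only (augmentation never sees the
#' held-out fold), the workload is tuned on the augmented training data via
#' its inner CV, and ROC-AUC is measured on the held-out fold. The final
#' ROC-AUC per (generator, n') is the mean over outer folds; the pair
#' maximizing it defines the best generator and `n'_max` (smallest n' on
#' ties). The baseline is the fold-averaged ROC-AUC of the un-augmented
#' training partitions, and the reported diversity is the fold-averaged
#' diversity of the winning augmentation.
#'
#' @param data A `tabaug_dataset`.
#' @param generators Character vector of generator methods.
#' @param n_prime_grid Synthetic-data sizes to evaluate.
#' @param settings Workload settings.
#' @param seed Integer seed.
#' @param n_folds Outer folds (default 5).
#' @param diversity_trees Trees for the diversity forest (default 100).
#' @return An object of class `tabaug_case_study`: list with `dataset_id`,
#'   `best_generator`, `n_prime_max`, `baseline_auc`, `augmented_auc`,
#'   `relative_improvement`, `diversity_generative`, `auc_table` (mean AUC
#'   per generator x n'), `profiles` (per-fold complexity profiles) and the
#'   fold definition.
#' @export
nested_cv_evaluate <- function(data, generators = c("seq_trees", "bayes_net"),
                               n_prime_grid = default_n_prime_grid(),
                               settings = workload_settings(), seed = 1L,
                               n_folds = 5L, diversity_trees = 100L) {
  y <- outcome01(data)
  if (min(table(y)) < n_folds)
    stop("each outcome class needs >= n_folds rows")
  folds <- outer_folds(y, n_folds, seed)
  n_prime_grid <- as.integer(n_prime_grid)

  baseline_by_fold <- numeric(n_folds)
  auc <- array(NA_real_, dim = c(length(generators), length(n_prime_grid),
                                 n_folds),
               dimnames = list(generators, as.character(n_prime_grid), NULL))
  profiles <- vector("list", n_folds)
  fitted_gens <- vector("list", n_folds)

  for (f in seq_len(n_folds)) {
    test_idx <- folds[[f]]
    tr <- subset_rows(data, setdiff(seq_along(y), test_idx),
                      id = paste0(data$id, "_fold", f))
    te <- subset_rows(data, test_idx)
    base_fit <- train_workload(tr, settings)
    baseline_by_fold[f] <- evaluate_auc(base_fit, te)
    profiles[[f]] <- profile_dataset(tr, baseline_auc = baseline_by_fold[f])
    fitted_gens[[f]] <- lapply(stats::setNames(generators, generators),
                               function(g) tryCatch(fit_generator(g, tr),
                                                    error = function(e) NULL))
    for (g in generators) {
      model <- fitted_gens[[f]][[g]]
      if (is.null(model)) next
      for (j in seq_along(n_prime_grid)) {
        auc[g, j, f] <- tryCatch({
          aug <- augment(tr, model, n_prime_grid[j],
                         seed = seed + f * 1000L + j)
          evaluate_auc(train_workload(aug, settings), te)
        }, error = function(e) NA_real_)
      }
    }
  }

  mean_auc <- apply(auc, c(1L, 2L), mean)
  baseline_auc <- mean(baseline_by_fold)
  best <- which(mean_auc == max(mean_auc, na.rm = TRUE), arr.ind = TRUE)
  # smallest n' among maxima, then first generator
  best <- best[order(n_prime_grid[best[, 2L]], best[, 1L]), , drop = FALSE][1L, ]
  best_gen <- generators[best[1L]]
  n_prime_max <- n_prime_grid[best[2L]]
  augmented_auc <- mean_auc[best[1L], best[2L]]

  div <- vapply(seq_len(n_folds), function(f) {
    model <- fitted_gens[[f]][[best_gen]]
    if (is.null(model)) return(NA_real_)
    tr <- subset_rows(data, setdiff(seq_along(y), folds[[f]]))
    aug <- augment(tr, model, n_prime_max, seed = seed + f * 1000L)
    dataset_diversity(tr, aug, n_trees = diversity_trees,
                      seed = seed + f)$diversity
  }, numeric(1L))

  structure(list(dataset_id = data$id, best_generator = best_gen,
                 n_prime_max = n_prime_max, baseline_auc = baseline_auc,
                 augmented_auc = augmented_auc,
                 relative_improvement =
                   relative_improvement(baseline_auc, augmented_auc),
                 diversity_generative = mean(div, na.rm = TRUE),
                 auc_table = mean_auc, baseline_by_fold = baseline_by_fold,
                 profiles = do.call(rbind, profiles), folds = folds,
                 n_prime_grid = n_prime_grid, seed = seed,
                 settings = settings),
            class = "tabaug_case_study")
}

#' @export
print.tabaug_case_study <- function(x, ...) {
  cat(sprintf(
    "<tabaug_case_study> '%s': baseline %.4f -> augmented %.4f (%+.2f%%)\n",
    x$dataset_id, x$baseline_auc, x$augmented_auc, x$relative_improvement))
  cat(sprintf("  best generator %s at n' = %d; diversity %.4f\n",
              x$best_generator, x$n_prime_max, x$diversity_generative))
  invisible(x)
}

#' Bootstrap resampling comparison at the selected synthetic-data size
#'
#' Repeats the nested CV of a prior [nested_cv_evaluate()] using the
#' bootstrap generator at exactly `n' = n_prime_max`, reusing the same fold
#' definition, and returns the fold-averaged ROC-AUC and diversity of the
#' resampling-augmented data.
#'
#' @param data The same `tabaug_dataset`.
#' @param result The `tabaug_case_study` whose folds and `n_prime_max` are
#'   reused.
#' @param settings Workload settings (default: the ones stored in
#'   `result`).
#' @param diversity_trees Trees for the diversity forest (default 100).
#' @return List with `resampled_auc` and `diversity_resample`.
#' @export
resampling_comparison <- function(data, result, settings = result$settings,
                                  diversity_trees = 100L) {
  stopifnot(inherits(result, "tabaug_case_study"))
  folds <- result$folds
  y <- outcome01(data)
  aucs <- numeric(length(folds)); divs <- numeric(length(folds))
  for (f in seq_along(folds)) {
    tr <- subset_rows(data, setdiff(seq_along(y), folds[[f]]))
    te <- subset_rows(data, folds[[f]])
    model <- fit_bootstrap(tr)
    aug <- augment(tr, model, result$n_prime_max,
                   seed = result$seed + f * 1000L)
    aucs[f] <- evaluate_auc(train_workload(aug, settings), te)
    divs[f] <- dataset_diversity(tr, aug, n_trees = diversity_trees,
                                 seed = result$seed + f)$diversity
  }
  list(resampled_auc = mean(aucs), diversity_resample = mean(divs))
}
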