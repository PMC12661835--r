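# The prognostic workload: a gradient-boosted decision tree classifier with
# target-encoded categoricals, seeded random-search tuning over an inner
# stratified CV, and rank-based ROC-AUC evaluation.

#' Workload settings
#'
#' @param tuning_budget Number of hyperparameter candidates evaluated
#'   (default 30; use a small budget for quick runs).
#' @param inner_folds Inner cross-validation folds for tuning (default 5).
#' @param nrounds Boosting rounds (default 200).
#' @param param_space Named list of ranges; see [default_param_space()].
#' @param smoothing Target-encoding shrinkage (default 10).
#' @param seed Integer seed controlling candidate draws, fold assignment and
#'   the booster RNG.
#' @return An object of class `tabaug_workload_settings`.
#' @export
workload_settings <- function(tuning_budget = 30L, inner_folds = 5L,
                              nrounds = 200L,
                              param_space = default_param_space(),
                              smoothing = 10, seed = 1L) {
  stopifnot(tuning_budget >= 1L, inner_folds >= 2L, nrounds >= 1L)
  structure(list(tuning_budget = as.integer(tuning_budget),
                 inner_folds = as.integer(inner_folds),
                 nrounds = as.integer(nrounds), param_space = param_space,
                 smoothing = smoothing, seed = as.integer(seed)),
            class = "tabaug_workload_settings")
}

#' Default hyperparameter search space
#'
#' Conventional GBDT tuning ranges: learning rate log-uniform on
#' \[0.01, 0.3\], tree depth \[3, 12\], minimum child weight \[5, 50\], row
#' and feature subsampling \[0.6, 1\], L1/L2 regularization log-uniform on
#' \[1e-8, 10\].
#'
#' @return Named list of `c(lo, hi)` ranges with a `log` attribute listing
#'   the log-uniform dimensions.
#' @export
default_param_space <- function() {
  space <- list(eta = c(0.01, 0.3), max_depth = c(3, 12),
                min_child_samples = c(5, 50), subsample = c(0.6, 1),
                colsample_bytree = c(0.6, 1), alpha = c(1e-8, 10),
                lambda = c(1e-8, 10))
  attr(space, "log") <- c("eta", "alpha", "lambda")
  attr(space, "integer") <- c("max_depth")
  space
}

draw_params <- function(space) {
  logd <- attr(space, "log"); intd <- attr(space, "integer")
  out <- lapply(names(space), function(nm) {
    r <- space[[nm]]
    v <- if (nm %in% logd) exp(stats::runif(1L, log(r[1L]), log(r[2L])))
         else stats::runif(1L, r[1L], r[2L])
    if (nm %in% intd) v <- as.integer(round(v))
    v
  })
  stats::setNames(out, names(space))
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    rows <- which(y == cl)
    rows <- rows[sample.int(length(rows))]
    fold[rows] <- rep_len(seq_len(k), length(rows))
  }
  fold
}

xgb_fit <- function(X, y, params, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  if (!is.null(params$min_child_samples)) {
    # tuned as a record count; xgboost measures child size in hessian units,
    # bounded by 0.25 per record for the logistic objective
    params$min_child_weight <- 0.25 * params$min_child_samples
    params$min_child_samples <- NULL
  }
  full <- c(list(objective = "binary:logistic", eval_metric = "auc",
                 nthread = 1L, tree_method = "hist"), params)
  set.seed(as.integer(seed) %% .Machine$integer.max)  # booster subsampling RNG
  xgboost::xgb.train(params = full, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

#' Train the prognostic workload on a dataset
#'
#' Categoricals are target-encoded with statistics fitted on the training
#' rows only. Hyperparameters are chosen by seeded random search over
#' `tuning_budget` candidates, each scored by mean ROC-AUC over an
#' outcome-stratified inner cross-validation; the winning candidate is refit
#' on all training rows.
#'
#' @param train A `tabaug_dataset` with both outcome classes present.
#' @param settings A `tabaug_workload_settings`.
#' @return An object of class `tabaug_workload` with a `predict` method
#'   returning positive-class probabilities.
#' @export
train_workload <- function(train, settings = workload_settings()) {
  stopifnot(inherits(train, "tabaug_dataset"),
            inherits(settings, "tabaug_workload_settings"))
  y <- outcome01(train)
  if (length(unique(y)) < 2L) stop("training data has a single outcome class")
  enc <- target_encoder(train, smoothing = settings$smoothing)
  X <- predict(enc, train)

  local_rng(settings$seed)
  candidates <- lapply(seq_len(settings$tuning_budget), function(i)
    draw_params(settings$param_space))
  k <- min(settings$inner_folds, min(table(y)))
  tuned <- if (k >= 2L && settings$tuning_budget > 1L) {
    fold <- stratified_folds(y, k)
    cv_auc <- vapply(candidates, function(par) {
      aucs <- vapply(seq_len(k), function(f) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
          return(NA_real_)
        fit <- xgb_fit(X[tr, , drop = FALSE], y[tr], par, settings$nrounds,
                       settings$seed)
        roc_auc(predict(fit, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE])),
                y[!tr])
      }, numeric(1L))
      mean(aucs, na.rm = TRUE)
    }, numeric(1L))
    candidates[[which.max(cv_auc)]]
  } else candidates[[1L]]

  booster <- xgb_fit(X, y, tuned, settings$nrounds, settings$seed)
  structure(list(booster = booster, encoder = enc, params = tuned,
                 settings = settings, n = nrow(train$data)),
            class = "tabaug_workload")
}

#' @export
predict.tabaug_workload <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "tabaug_dataset"))
  X <- predict(object$encoder, newdata)
  predict(object$booster, xgboost::xgb.DMatrix(X))
}

#' @export
print.tabaug_workload <- function(x, ...) {
  cat(sprintf("<tabaug_workload> GBDT fitted on %d rows (eta=%.3f, depth=%d)\n",
              x$n, x$params$eta, x$params$max_depth))
  invisible(x)
}

#' Rank-based ROC-AUC
#'
#' The probability that a random positive outranks a random negative, with
#' ties contributing 1/2 — i.e. the Mann-Whitney U statistic scaled by the
#' number of positive-negative pairs.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 outcome labels (both classes present).
#' @return ROC-AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a fitted workload on held-out data
#'
#' @param model A `tabaug_workload`.
#' @param test A `tabaug_dataset` sharing the training schema, with both
#'   classes present.
#' @return ROC-AUC in \[0, 1\].
#' @export
evaluate_auc <- function(model, test) {
  y <- outcome01(test)
  if (length(unique(y)) < 2L) stop("test data has a single outcome class")
  roc_auc(predict(model, test), y)
}
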