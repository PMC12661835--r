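# The eight dataset characteristics fed to the augmentation-benefit model:
# base size, predictor degrees of freedom, outcome imbalance, mean
# standardized entropy, dispersion of pairwise mutual information,
# Gower-distance class separability, baseline ROC-AUC, predictor count.

#' Outcome imbalance factor
#'
#' `max(p / (1 - p), (1 - p) / p)` for prevalence `p`; 1 means balanced.
#'
#' @param outcome A 0/1 vector (or a `tabaug_dataset`).
#' @return Ratio >= 1.
#' @export
imbalance_factor <- function(outcome) {
  if (inherits(outcome, "tabaug_dataset")) outcome <- outcome01(outcome)
  p <- mean(outcome)
  if (p <= 0 || p >= 1) stop("outcome must contain both classes")
  max(p / (1 - p), (1 - p) / p)
}

#' Predictor degrees of freedom
#'
#' A numeric predictor contributes 1; a categorical predictor with `k`
#' declared levels contributes `k - 1`.
#'
#' @param schema A `tabaug_schema` (or a `tabaug_dataset`).
#' @return Integer count.
#' @export
degrees_of_freedom <- function(schema) {
  if (inherits(schema, "tabaug_dataset")) schema <- schema$schema
  sum(vapply(predictor_names(schema), function(nm) {
    if (var_kind(schema, nm) == "numeric") 1L
    else length(var_levels(schema, nm)) - 1L
  }, integer(1L)))
}

# Equal-frequency discretization used by the entropy and MI characteristics.
discretize_column <- function(col, n_bins) {
  if (is.numeric(col)) {
    x <- col[!is.na(col)]
    edges <- unique(stats::quantile(col, probs = seq(0, 1, length.out = n_bins + 1L),
                                    na.rm = TRUE, names = FALSE, type = 7))
    if (length(edges) < 2L) return(factor(rep("b1", length(col))))
    out <- cut(col, breaks = edges, include.lowest = TRUE)
    out <- addNA(out, ifany = TRUE)
    out
  } else {
    droplevels(as.factor(col))
  }
}

shannon_entropy <- function(freq) {
  p <- freq[freq > 0] / sum(freq)
  -sum(p * log(p))
}

#' Mean standardized entropy of the predictors
#'
#' Each predictor's Shannon entropy (over equal-frequency bins for numerics,
#' observed levels for categoricals) is divided by `log(k)`; a predictor with
#' a single observed level contributes 0. The mean across predictors lies in
#' \[0, 1\].
#'
#' @param data A `tabaug_dataset`.
#' @param n_bins Bins per numeric predictor (default 10).
#' @return Mean normalized entropy in \[0, 1\].
#' @export
standardized_entropy <- function(data, n_bins = 10L) {
  preds <- predictor_names(data$schema)
  if (length(preds) < 1L) stop("no predictors in schema")
  vals <- vapply(preds, function(nm) {
    f <- table(discretize_column(data$data[[nm]], n_bins))
    f <- f[f > 0]
    k <- length(f)
    if (k <= 1L) return(0)
    shannon_entropy(f) / log(k)
  }, numeric(1L))
  mean(vals)
}

# Plug-in mutual information (natural log) of two discretized columns.
plugin_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  nz <- tab > 0
  pij <- tab[nz] / n
  sum(pij * log(pij / (pj[row(tab)[nz]] * pk[col(tab)[nz]])))
}

#' Coefficient of variation of pairwise predictor mutual information
#'
#' Plug-in MI is computed on the discretized contingency table of every
#' unordered predictor pair; the statistic is the sample standard deviation
#' divided by the mean across pairs.
#'
#' @param data A `tabaug_dataset` with >= 2 predictors.
#' @param n_bins Bins per numeric predictor (default 10).
#' @return CV >= 0; returns 0 with a warning when the mean MI is 0.
#' @export
mutual_info_cv <- function(data, n_bins = 10L) {
  preds <- predictor_names(data$schema)
  if (length(preds) < 2L) stop("mutual_info_cv needs >= 2 predictors")
  cols <- lapply(preds, function(nm) discretize_column(data$data[[nm]], n_bins))
  pairs <- utils::combn(length(preds), 2L)
  mi <- apply(pairs, 2L, function(ij) plugin_mi(cols[[ij[1L]]], cols[[ij[2L]]]))
  m <- mean(mi)
  if (m <= .Machine$double.eps) {
    warning("mean pairwise MI is zero; returning CV = 0")
    return(0)
  }
  stats::sd(mi) / m
}

# Per-variable building blocks of the Gower distance over predictors.
gower_parts <- function(data) {
  preds <- predictor_names(data$schema)
  ranges <- list()
  for (nm in preds) {
    if (var_kind(data$schema, nm) == "numeric") {
      r <- range(data$data[[nm]], na.rm = TRUE)
      ranges[[nm]] <- r[2L] - r[1L]
    }
  }
  ranges
}

#' Gower distance between two records
#'
#' Mean over predictors of `|a_i - b_i| / range_i` for numerics and the
#' mismatch indicator for categoricals. Zero-range numerics contribute 0.
#'
#' @param a,b Single-row data frames (or list-like records) over the
#'   schema's predictors.
#' @param schema The shared `tabaug_schema`.
#' @param ranges Named list of observed numeric ranges (from the reference
#'   dataset).
#' @return Distance in \[0, 1\].
#' @export
gower_distance <- function(a, b, schema, ranges) {
  preds <- predictor_names(schema)
  d <- vapply(preds, function(nm) {
    if (var_kind(schema, nm) == "numeric") {
      r <- ranges[[nm]]
      if (is.null(r) || r <= 0) return(0)
      min(1, abs(as.numeric(a[[nm]]) - as.numeric(b[[nm]])) / r)
    } else {
      as.numeric(as.character(a[[nm]]) != as.character(b[[nm]]))
    }
  }, numeric(1L))
  mean(d)
}

# Full pairwise Gower matrix over predictors (vectorized per variable).
gower_matrix <- function(data) {
  preds <- predictor_names(data$schema)
  n <- nrow(data$data)
  acc <- matrix(0, n, n)
  ranges <- gower_parts(data)
  for (nm in preds) {
    col <- data$data[[nm]]
    if (var_kind(data$schema, nm) == "numeric") {
      r <- ranges[[nm]]
      if (is.null(r) || r <= 0 || !is.finite(r)) next
      x <- as.numeric(col)
      x[is.na(x)] <- stats::median(x, na.rm = TRUE)
      acc <- acc + pmin(1, abs(outer(x, x, "-")) / r)
    } else {
      x <- as.character(col)
      acc <- acc + (outer(x, x, "!=")) * 1
    }
  }
  acc / length(preds)
}

#' Gower-distance class separability
#'
#' For each record, the Gower distance to its nearest same-class neighbor
#' (excluding itself) and to its nearest other-class neighbor are found; the
#' statistic is `mean(d_intra) / mean(d_inter)`. Lower values mean the
#' classes are easier to tell apart.
#'
#' @param data A `tabaug_dataset` with >= 2 rows in each outcome class.
#' @param max_rows Subsample cap for the O(n^2) distance matrix
#'   (default 2000); subsampling is outcome-stratified and seeded.
#' @param seed Seed for the subsample.
#' @return Positive ratio.
#' @export
separability <- function(data, max_rows = 2000L, seed = 1L) {
  y <- outcome01(data)
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop("both classes need >= 2 rows")
  if (nrow(data$data) > max_rows) {
    local_rng(seed)
    idx <- unlist(lapply(c(0L, 1L), function(cl) {
      rows <- which(y == cl)
      k <- max(2L, round(max_rows * length(rows) / length(y)))
      sample(rows, min(length(rows), k))
    }))
    data <- subset_rows(data, sort(idx))
    y <- outcome01(data)
  }
  G <- gower_matrix(data)
  diag(G) <- Inf
  n <- length(y)
  same <- outer(y, y, "==")
  d_intra <- vapply(seq_len(n), function(i)
    min(G[i, same[i, ] & seq_len(n) != i]), numeric(1L))
  d_inter <- vapply(seq_len(n), function(i) min(G[i, !same[i, ]]), numeric(1L))
  mi <- mean(d_inter)
  if (mi <= 0) stop("mean interclass nearest-neighbor distance is zero")
  mean(d_intra) / mi
}

#' Assemble the eight-characteristic complexity profile of a base dataset
#'
#' @param base Base `tabaug_dataset`.
#' @param test Held-out `tabaug_dataset` used for the baseline ROC-AUC
#'   (ignored when `baseline_auc` is supplied).
#' @param settings Workload settings from [workload_settings()].
#' @param baseline_auc Optional precomputed baseline ROC-AUC (e.g. the
#'   fold-averaged baseline in the nested-CV case study).
#' @param n_bins Discretization grain for entropy/MI (default 10).
#' @return A one-row data frame of class `tabaug_profile` with columns
#'   `n0, degrees_of_freedom, imbalance_factor, std_entropy, mi_cv,
#'   separability, baseline_auc, n_predictors` plus `dataset_id`.
#' @export
profile_dataset <- function(base, test = NULL, settings = workload_settings(),
                            baseline_auc = NULL, n_bins = 10L) {
  if (is.null(baseline_auc)) {
    if (is.null(test)) stop("either test data or baseline_auc is required")
    fit <- train_workload(base, settings)
    baseline_auc <- evaluate_auc(fit, test)
  }
  out <- data.frame(
    dataset_id = base$id,
    n0 = nrow(base$data),
    degrees_of_freedom = degrees_of_freedom(base$schema),
    imbalance_factor = imbalance_factor(base),
    std_entropy = standardized_entropy(base, n_bins),
    mi_cv = if (length(predictor_names(base$schema)) >= 2L)
      suppressWarnings(mutual_info_cv(base, n_bins)) else 0,
    separability = separability(base),
    baseline_auc = baseline_auc,
    n_predictors = length(predictor_names(base$schema)),
    stringsAsFactors = FALSE)
  class(out) <- c("tabaug_profile", class(out))
  out
}
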