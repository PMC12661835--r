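# Diversity of an augmented dataset relative to its base: anomaly scores
# from an extended isolation forest trained on the base, contamination
# curves over a fixed threshold grid, and a weighted positive-difference
# score in [0, 1].

TAU_GRID <- seq(0.01, 1, by = 0.01)

# Harmonic-number based average unsuccessful-search path length of a BST.
eif_c <- function(n) {
  if (n <= 1) return(0)
  2 * (log(n - 1) + 0.5772156649015329) - 2 * (n - 1) / n
}

# Outcome-free numeric encoding for the forest: categorical levels map to
# their training frequency, numerics are min-max scaled on training bounds.
eif_encoder <- function(base) {
  sch <- base$schema
  nms <- schema_names(sch)
  maps <- list(); bounds <- list()
  for (nm in nms) {
    col <- base$data[[nm]]
    if (is.numeric(col)) {
      r <- range(col, na.rm = TRUE)
      if (!all(is.finite(r))) r <- c(0, 1)
      if (r[2L] <= r[1L]) r[2L] <- r[1L] + 1
      bounds[[nm]] <- r
    } else {
      f <- table(as.character(col)) / length(col)
      maps[[nm]] <- f
    }
  }
  med <- lapply(base$data, function(col)
    if (is.numeric(col)) stats::median(col, na.rm = TRUE) else NULL)
  list(maps = maps, bounds = bounds, medians = med, names = nms)
}

eif_encode <- function(enc, ds) {
  out <- matrix(0, nrow(ds$data), length(enc$names),
                dimnames = list(NULL, enc$names))
  for (nm in enc$names) {
    col <- ds$data[[nm]]
    if (is.numeric(col)) {
      x <- as.numeric(col)
      x[is.na(x)] <- enc$medians[[nm]]
      b <- enc$bounds[[nm]]
      out[, nm] <- (x - b[1L]) / (b[2L] - b[1L])
    } else {
      f <- enc$maps[[nm]]
      v <- unname(f[as.character(col)])
      v[is.na(v)] <- 0  # unseen level: frequency zero
      out[, nm] <- v
    }
  }
  out
}

grow_eif_tree <- function(X, idx, depth, limit) {
  n <- length(idx)
  if (depth >= limit || n <= 1L) return(list(leaf = TRUE, size = n))
  sub <- X[idx, , drop = FALSE]
  if (all(apply(sub, 2L, function(c) diff(range(c)) == 0)))
    return(list(leaf = TRUE, size = n))
  d <- ncol(X)
  for (try in 1:5) {
    normal <- stats::rnorm(d)
    proj <- drop(sub %*% normal)
    rng <- range(proj)
    if (diff(rng) > 0) break
  }
  if (diff(rng) == 0) return(list(leaf = TRUE, size = n))
  thr <- stats::runif(1L, rng[1L], rng[2L])
  left <- proj < thr
  if (all(left) || !any(left)) return(list(leaf = TRUE, size = n))
  list(leaf = FALSE, normal = normal, thr = thr,
       left = grow_eif_tree(X, idx[left], depth + 1L, limit),
       right = grow_eif_tree(X, idx[!left], depth + 1L, limit))
}

eif_path_lengths <- function(tree, X, idx = seq_len(nrow(X)), depth = 0) {
  out <- numeric(nrow(X))
  rec <- function(node, idx, depth) {
    if (!length(idx)) return()
    if (node$leaf) {
      out[idx] <<- depth + eif_c(node$size)
      return()
    }
    proj <- drop(X[idx, , drop = FALSE] %*% node$normal)
    left <- proj < node$thr
    rec(node$left, idx[left], depth + 1)
    rec(node$right, idx[!left], depth + 1)
  }
  rec(tree, idx, depth)
  out
}

#' Fit an extended isolation forest on a base dataset
#'
#' Trees are grown on subsamples of the numerically encoded records using
#' random oblique (hyperplane) splits: a random normal vector over all
#' encoded dimensions and a uniform intercept within the node's projection
#' range. Depth is limited to `ceiling(log2(subsample))`. Anomaly scores use
#' the classic normalization `s = 2^(-E[h] / c(psi))`, so scores lie in
#' (0, 1) and the fixed threshold grid is meaningful.
#'
#' @param base A `tabaug_dataset` (or numeric matrix) with >= 2 rows.
#' @param n_trees Number of trees (default 200).
#' @param subsample Subsample size per tree, psi (default `min(256, n)`).
#' @param seed Integer seed.
#' @return An object of class `tabaug_eif` with a `predict` method returning
#'   scores.
#' @export
fit_eif <- function(base, n_trees = 200L, subsample = NULL, seed = 1L) {
  if (inherits(base, "tabaug_dataset")) {
    enc <- eif_encoder(base)
    X <- eif_encode(enc, base)
  } else {
    enc <- NULL
    X <- as.matrix(base)
  }
  n <- nrow(X)
  if (n < 2L) stop("need >= 2 training records")
  if (is.null(subsample)) subsample <- min(256L, n)
  if (subsample > n) stop("subsample exceeds number of records")
  local_rng(seed)
  limit <- ceiling(log2(subsample))
  trees <- lapply(seq_len(n_trees), function(t) {
    idx <- sample.int(n, subsample)
    grow_eif_tree(X, idx, 0L, limit)
  })
  structure(list(trees = trees, psi = subsample, n_trees = n_trees,
                 c_psi = eif_c(subsample), encoder = enc),
            class = "tabaug_eif")
}

#' @export
predict.tabaug_eif <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "tabaug_dataset")) {
    if (is.null(object$encoder)) stop("forest was fitted on a raw matrix")
    eif_encode(object$encoder, newdata)
  } else as.matrix(newdata)
  H <- matrix(0, nrow(X), length(object$trees))
  for (t in seq_along(object$trees))
    H[, t] <- eif_path_lengths(object$trees[[t]], X)
  2^(-rowMeans(H) / object$c_psi)
}

#' Contamination curve of a score vector
#'
#' For each threshold tau on the fixed grid 0.01, 0.02, ..., 1.00, the
#' contamination rate is the proportion of records whose anomaly score is
#' greater than or equal to tau.
#'
#' @param scores Non-empty numeric vector of anomaly scores.
#' @return An object of class `tabaug_curve`: list with `thresholds` and
#'   `rates` (monotone non-increasing).
#' @export
contamination_curve <- function(scores) {
  if (!length(scores)) stop("empty score vector")
  rates <- vapply(TAU_GRID, function(t) mean(scores >= t - 1e-12), numeric(1L))
  structure(list(thresholds = TAU_GRID, rates = rates), class = "tabaug_curve")
}

#' Diversity score from two contamination curves
#'
#' With `x_j` the augmented-minus-base contamination-rate difference at
#' threshold `tau_j`, the diversity is
#' `mean_j( x_j * (2 - x_j) )` over the thresholds where `x_j >= 0`, with
#' zero contribution where `x_j < 0`. The score lies in \[0, 1\] and is 0
#' when the curves coincide.
#'
#' @param base_curve,aug_curve `tabaug_curve` objects on the same grid.
#' @return An object of class `tabaug_diversity`: list with `x` (the 100
#'   rate differences) and `diversity`.
#' @export
diversity_score <- function(base_curve, aug_curve) {
  if (!isTRUE(all.equal(base_curve$thresholds, aug_curve$thresholds)))
    stop("threshold grids differ")
  x <- aug_curve$rates - base_curve$rates
  terms <- ifelse(x >= 0, x * (2 - x), 0)
  structure(list(x = x, diversity = mean(terms)), class = "tabaug_diversity")
}

#' @export
print.tabaug_diversity <- function(x, ...) {
  cat(sprintf("<tabaug_diversity> %.4f (positive at %d/100 thresholds)\n",
              x$diversity, sum(x$x > 0)))
  invisible(x)
}

#' Diversity of an augmented dataset relative to its base
#'
#' Fits the extended isolation forest on the base only, scores both
#' datasets, builds their contamination curves, and returns the weighted
#' positive-difference diversity.
#'
#' @param base Base `tabaug_dataset`.
#' @param augmented Augmented `tabaug_dataset` (same schema; typically the
#'   base rows plus synthetic rows).
#' @param n_trees,subsample,seed Forest settings, see [fit_eif()].
#' @return A `tabaug_diversity`.
#' @export
dataset_diversity <- function(base, augmented, n_trees = 200L,
                              subsample = NULL, seed = 1L) {
  stopifnot(identical(schema_names(base$schema),
                      schema_names(augmented$schema)))
  forest <- fit_eif(base, n_trees = n_trees, subsample = subsample, seed = seed)
  s_base <- predict(forest, base)
  s_aug <- predict(forest, augmented)
  diversity_score(contamination_curve(s_base), contamination_curve(s_aug))
}
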