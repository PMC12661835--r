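# Synthetic populations with the statistical shape of tabular clinical data:
# a latent Gaussian copula drives mixed-type predictors, and a logistic model
# on the latent coordinates drives a binary outcome with calibrated prevalence.

#' Configure a synthetic population
#'
#' The generator draws a latent multivariate Gaussian with exchangeable (or
#' arbitrary) correlation. Numeric predictors are latent coordinates;
#' categorical predictors slice their latent coordinate into `k` levels at
#' quantile boundaries (equal-probability by default, or Zipf-weighted to
#' emulate the imbalanced high-cardinality variables of administrative health
#' data). The outcome is Bernoulli with logit equal to a linear combination
#' of the latent coordinates plus noise; the intercept is calibrated by
#' bisection so the empirical prevalence approaches the target.
#'
#' @param n_rows Number of records.
#' @param numeric_vars Number of numeric predictors.
#' @param categorical_cardinalities Integer vector; one entry per categorical
#'   predictor giving its number of levels (each >= 2).
#' @param prevalence Target positive-outcome prevalence in (0, 1).
#' @param latent_correlation Either a single exchangeable correlation in
#'   [0, 1) or a full positive semi-definite correlation matrix.
#' @param coefficients Log-odds effect of each predictor's latent coordinate
#'   on the outcome (length = total predictors; recycled if scalar).
#' @param noise_scale SD of additive logit noise (default 1).
#' @param level_weights `"equal"` for equal-probability level slicing or
#'   `"zipf"` for rank-weighted (probability of level r proportional to 1/r).
#' @param seed Integer seed.
#' @return An object of class `tabaug_popconfig`.
#' @export
population_config <- function(n_rows, numeric_vars = 3L,
                              categorical_cardinalities = c(2L, 4L),
                              prevalence = 0.3, latent_correlation = 0.3,
                              coefficients = 0.5, noise_scale = 1,
                              level_weights = c("equal", "zipf"),
                              seed = 1L) {
  level_weights <- match.arg(level_weights)
  p <- numeric_vars + length(categorical_cardinalities)
  stopifnot(n_rows >= 1, p >= 1, prevalence > 0, prevalence < 1,
            noise_scale >= 0,
            all(categorical_cardinalities >= 2L))
  if (length(coefficients) == 1L) coefficients <- rep(coefficients, p)
  stopifnot(length(coefficients) == p)
  if (is.matrix(latent_correlation)) {
    stopifnot(nrow(latent_correlation) == p,
              isSymmetric(unname(latent_correlation)))
    ev <- eigen(latent_correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("latent correlation matrix is not PSD")
  } else {
    stopifnot(latent_correlation >= 0, latent_correlation < 1)
  }
  structure(list(n_rows = as.integer(n_rows),
                 numeric_vars = as.integer(numeric_vars),
                 categorical_cardinalities = as.integer(categorical_cardinalities),
                 prevalence = prevalence,
                 latent_correlation = latent_correlation,
                 coefficients = coefficients, noise_scale = noise_scale,
                 level_weights = level_weights, seed = as.integer(seed)),
            class = "tabaug_popconfig")
}

zipf_probs <- function(k) { w <- 1 / seq_len(k); w / sum(w) }

#' Generate a synthetic population dataset
#'
#' @param config A `tabaug_popconfig` from [population_config()].
#' @return A `tabaug_dataset` with numeric predictors `num1..`, categorical
#'   predictors `cat1..` and a binary outcome `outcome` with levels
#'   `c("neg", "pos")`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "tabaug_popconfig"))
  local_rng(config$seed)
  n <- config$n_rows
  cards <- config$categorical_cardinalities
  p <- config$numeric_vars + length(cards)

  R <- if (is.matrix(config$latent_correlation)) config$latent_correlation
       else {
         r <- config$latent_correlation
         m <- matrix(r, p, p); diag(m) <- 1; m
       }
  L <- tryCatch(chol(R), error = function(e) {
    # PSD but rank-deficient: bump the diagonal minimally
    chol(R + diag(1e-8, p))
  })
  Z <- matrix(stats::rnorm(n * p), n, p) %*% L

  df <- list()
  idx <- 1L
  for (j in seq_len(config$numeric_vars)) {
    df[[paste0("num", j)]] <- Z[, idx]
    idx <- idx + 1L
  }
  for (j in seq_along(cards)) {
    k <- cards[j]
    probs <- if (config$level_weights == "zipf") zipf_probs(k) else rep(1 / k, k)
    breaks <- stats::qnorm(cumsum(probs)[-k])
    lev_idx <- findInterval(Z[, idx], breaks) + 1L
    labels <- sprintf("L%02d", seq_len(k))
    df[[paste0("cat", j)]] <- labels[lev_idx]
    idx <- idx + 1L
  }

  eta <- drop(Z %*% config$coefficients)
  if (config$noise_scale > 0) eta <- eta + stats::rnorm(n, sd = config$noise_scale)
  alpha <- calibrate_intercept(eta, config$prevalence)
  y <- stats::rbinom(n, 1L, stats::plogis(alpha + eta))
  df[["outcome"]] <- c("neg", "pos")[y + 1L]

  vars <- c(
    lapply(seq_len(config$numeric_vars), function(j)
      var_spec(paste0("num", j), "numeric")),
    lapply(seq_along(cards), function(j)
      var_spec(paste0("cat", j), "categorical",
               levels = sprintf("L%02d", seq_len(cards[j])))),
    list(var_spec("outcome", "categorical", levels = c("neg", "pos"),
                  role = "outcome"))
  )
  dataset(as.data.frame(df, stringsAsFactors = FALSE), schema(vars),
          id = "synthetic_population")
}

# Bisection on the logistic intercept so that mean plogis(alpha + eta)
# matches the target prevalence to 1e-3 (in expectation over eta).
calibrate_intercept <- function(eta, prevalence, tol = 1e-3) {
  f <- function(a) mean(stats::plogis(a + eta)) - prevalence
  lo <- -30; hi <- 30
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) < tol * 1e-2) break
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  mid
}

#' Preset population configurations
#'
#' Two reference complexity regimes: `"simple"` emulates a survey-like
#' dataset with six low-cardinality predictors, `"complex"` emulates an
#' administrative adverse-event-style dataset with seven predictors of which
#' several are high-cardinality categoricals with Zipf-imbalanced levels.
#'
#' @param name `"simple"` or `"complex"`.
#' @param n_rows Population size (default 50000).
#' @param seed Integer seed.
#' @return A `tabaug_popconfig`.
#' @export
preset_population <- function(name = c("simple", "complex"),
                              n_rows = 50000L, seed = 1L) {
  name <- match.arg(name)
  if (name == "simple") {
    population_config(
      n_rows = n_rows, numeric_vars = 3L,
      categorical_cardinalities = c(2L, 3L, 5L),
      prevalence = 0.3, latent_correlation = 0.3,
      coefficients = c(0.8, -0.5, 0.3, 0.4, -0.3, 0.2),
      noise_scale = 1, level_weights = "equal", seed = seed)
  } else {
    population_config(
      n_rows = n_rows, numeric_vars = 2L,
      categorical_cardinalities = c(2L, 6L, 20L, 50L, 100L),
      prevalence = 0.15, latent_correlation = 0.25,
      coefficients = c(0.7, -0.4, 0.3, -0.4, 0.5, 0.6, -0.5),
      noise_scale = 1, level_weights = "zipf", seed = seed)
  }
}
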