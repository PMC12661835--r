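# Shared in-code fixtures: tiny schemas, datasets and fast workload settings.

toy_schema <- function() {
  schema(var_spec("age", "numeric"),
         var_spec("sex", "categorical", levels = c("M", "F")),
         var_spec("outcome", "categorical", levels = c("0", "1"),
                  role = "outcome"))
}

toy_dataset <- function(n = 12L, seed = 1L) {
  set.seed(seed)
  dataset(data.frame(age = round(rnorm(n, 50, 10), 2),
                     sex = sample(c("M", "F"), n, TRUE),
                     outcome = sample(c("0", "1"), n, TRUE),
                     stringsAsFactors = FALSE),
          toy_schema(), id = "toy")
}

# single binary predictor dataset with optional deterministic copy outcome
binary_pair_dataset <- function(n, p = 0.3, copy = FALSE, seed = 1L) {
  set.seed(seed)
  x <- rbinom(n, 1L, p)
  y <- if (copy) x else rbinom(n, 1L, 0.5)
  dataset(data.frame(x = as.character(x), outcome = as.character(y),
                     stringsAsFactors = FALSE),
          schema(var_spec("x", "categorical", levels = c("0", "1")),
                 var_spec("outcome", "categorical", levels = c("0", "1"),
                          role = "outcome")),
          id = "binary_pair")
}

# two numeric clusters per class, controllable separation
two_cluster_dataset <- function(n_per_class = 40L, spacing = 2, seed = 1L) {
  set.seed(seed)
  x <- c(rnorm(n_per_class, 0, 0.5), rnorm(n_per_class, spacing, 0.5))
  y <- rep(c("neg", "pos"), each = n_per_class)
  dataset(data.frame(x = x, outcome = y, stringsAsFactors = FALSE),
          schema(var_spec("x", "numeric"),
                 var_spec("outcome", "categorical", levels = c("neg", "pos"),
                          role = "outcome")),
          id = "two_cluster")
}

fast_settings <- function(seed = 1L, budget = 3L) {
  workload_settings(tuning_budget = budget, inner_folds = 3L, nrounds = 40L,
                    seed = seed)
}

# small mixed-type population for pipeline tests
small_population <- function(n = 4000L, seed = 7L) {
  generate_population(population_config(
    n_rows = n, numeric_vars = 2L, categorical_cardinalities = c(2L, 4L),
    prevalence = 0.3, latent_correlation = 0.3,
    coefficients = c(0.9, -0.6, 0.5, 0.5), noise_scale = 1, seed = seed))
}
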