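# Population-scale simulation grid: stratified base samples of 40 sizes,
# geometric augmentation-size series, and one workload evaluation per
# {n0, series, n', generator} cell against a single fixed test partition.

#' The default grid of base-dataset sizes
#'
#' 40 sizes: 20..100 by 10, 150..1000 by 50, 2000..10000 by 1000,
#' 20000..50000 by 10000.
#'
#' @return Integer vector of length 40.
#' @export
default_n0_values <- function() {
  c(seq(20L, 100L, 10L), seq(150L, 1000L, 50L),
    seq(2000L, 10000L, 1000L), seq(20000L, 50000L, 10000L))
}

#' Configure a simulation grid
#'
#' @param n0_values Strictly increasing base sizes (default the 40-value
#'   grid of [default_n0_values()]).
#' @param n_series Number of geometric series per n0 (default 10).
#' @param series_length Elements per series (default 30).
#' @param b_mean,b_sd Parameters of the normal draw of the geometric ratio
#'   `b` (defaults 1.5 and 0.005).
#' @param generators Character vector of generator methods to compare
#'   (subset of `"bootstrap"`, `"seq_trees"`, `"bayes_net"`).
#' @param per_element_b Draw a fresh `b` for every series element instead of
#'   one per series (default FALSE: one draw per series).
#' @param train_fraction Train share of the single population split
#'   (default 0.7).
#' @param seed Integer seed.
#' @return An object of class `tabaug_gridconfig`.
#' @export
grid_config <- function(n0_values = default_n0_values(), n_series = 10L,
                        series_length = 30L, b_mean = 1.5, b_sd = 0.005,
                        generators = c("seq_trees", "bayes_net", "bootstrap"),
                        per_element_b = FALSE, train_fraction = 0.7,
                        seed = 1L) {
  stopifnot(all(diff(n0_values) > 0), series_length >= 1L, n_series >= 1L,
            all(generators %in% c("bootstrap", "seq_trees", "bayes_net")))
  structure(list(n0_values = as.integer(n0_values),
                 n_series = as.integer(n_series),
                 series_length = as.integer(series_length),
                 b_mean = b_mean, b_sd = b_sd, generators = generators,
                 per_element_b = per_element_b,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "tabaug_gridconfig")
}

# round-half-away-from-zero, the bracket operator of the size series
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' One geometric series of synthetic-data sizes
#'
#' Draws `b ~ N(b_mean, b_sd)` (redrawn in the measure-zero event b <= 1)
#' and returns `round(b^(i+4))` for `i = 1..series_length`, so the series
#' concentrates sizes at the low end where augmentation effects vary most.
#'
#' @param config A `tabaug_gridconfig`.
#' @param series_seed Integer seed for the `b` draw(s).
#' @return Integer vector of length `series_length`.
#' @export
geometric_series <- function(config, series_seed = 1L) {
  local_rng(series_seed)
  i <- seq_len(config$series_length)
  if (config$per_element_b) {
    b <- stats::rnorm(length(i), config$b_mean, config$b_sd)
    while (any(b <= 1)) b[b <= 1] <- stats::rnorm(sum(b <= 1), config$b_mean,
                                                  config$b_sd)
  } else {
    b <- stats::rnorm(1L, config$b_mean, config$b_sd)
    while (b <= 1) b <- stats::rnorm(1L, config$b_mean, config$b_sd)
  }
  as.integer(round_half_away(b^(i + 4)))
}

#' Outcome-stratified base sample without replacement
#'
#' @param train Training `tabaug_dataset`.
#' @param n0 Base size (<= training rows, large enough to hold both
#'   classes).
#' @param seed Integer seed.
#' @return A `tabaug_dataset` of `n0` rows.
#' @export
draw_base <- function(train, n0, seed = 1L) {
  y <- outcome01(train)
  n <- length(y)
  if (n0 > n) stop("n0 exceeds training rows")
  n_pos <- round(n0 * mean(y))
  n_pos <- max(1L, min(n0 - 1L, n_pos))
  if (n_pos > sum(y == 1L) || (n0 - n_pos) > sum(y == 0L))
    stop("n0 cannot be stratified from this training set")
  local_rng(seed)
  idx <- c(sample(which(y == 1L), n_pos),
           sample(which(y == 0L), n0 - n_pos))
  subset_rows(train, sort(idx), id = paste0(train$id, "_n0_", n0))
}

fit_generator <- function(method, base) {
  switch(method,
         bootstrap = fit_bootstrap(base),
         seq_trees = fit_seq_trees(base),
         bayes_net = fit_bayes_net(base),
         stop("unknown generator method: ", method))
}

#' Run the augmentation simulation grid on one population
#'
#' Splits the population once (the same test partition is reused by every
#' cell), then for each base size draws a stratified base sample, computes
#' the baseline ROC-AUC of the un-augmented base, fits each generator on the
#' base only, and evaluates the workload on every augmented dataset of the
#' n0 x series x n' grid. Failed cells (e.g. degenerate synthetic outcomes)
#' are recorded with `failed = TRUE` rather than dropped.
#'
#' @param population A `tabaug_dataset`.
#' @param config A `tabaug_gridconfig`.
#' @param settings Workload settings.
#' @return A data frame of simulation records: `dataset_id, generator, n0,
#'   series_id, n_prime, auc, baseline_auc, failed`.
#' @export
run_grid <- function(population, config, settings = workload_settings()) {
  stopifnot(inherits(config, "tabaug_gridconfig"))
  sp <- split_population(population, config$train_fraction, seed = config$seed)
  series <- lapply(seq_len(config$n_series), function(s)
    geometric_series(config, series_seed = config$seed * 1000L + s))
  recs <- list()
  for (n0 in config$n0_values) {
    base <- draw_base(sp$train, n0, seed = config$seed + n0)
    baseline <- tryCatch({
      fit <- train_workload(base, settings)
      evaluate_auc(fit, sp$test)
    }, error = function(e) NA_real_)
    for (gen in config$generators) {
      model <- tryCatch(fit_generator(gen, base), error = function(e) NULL)
      for (s in seq_len(config$n_series)) {
        for (el in seq_len(config$series_length)) {
          n_prime <- series[[s]][el]
          cell_seed <- config$seed + n0 * 7L + s * 131L + el * 17L
          auc <- if (is.null(model)) NA_real_ else tryCatch({
            aug <- augment(base, model, n_prime, seed = cell_seed)
            fit <- train_workload(aug, settings)
            evaluate_auc(fit, sp$test)
          }, error = function(e) NA_real_)
          recs[[length(recs) + 1L]] <- data.frame(
            dataset_id = population$id, generator = gen, n0 = n0,
            series_id = s, n_prime = n_prime, auc = auc,
            baseline_auc = baseline, failed = is.na(auc),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, recs)
}

#' Cell counts implied by a grid configuration
#'
#' @param config A `tabaug_gridconfig`.
#' @param n_datasets Number of population datasets in the study.
#' @return List with `per_dataset` (cells per dataset per generator),
#'   `per_n0` (cells per n0 per generator) and `benefit_rows`
#'   (`n_datasets * length(n0_values)` rows per generator in the benefit
#'   table).
#' @export
grid_design_counts <- function(config, n_datasets = 13L) {
  cells <- expand.grid(n0 = config$n0_values,
                       series = seq_len(config$n_series),
                       element = seq_len(config$series_length))
  list(per_dataset = nrow(cells),
       per_n0 = nrow(cells[cells$n0 == config$n0_values[1L], ]),
       benefit_rows = n_datasets * length(config$n0_values))
}
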