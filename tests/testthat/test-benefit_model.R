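# build a toy record/profile pair with hand-set AUCs
toy_records <- function() {
  grid <- expand.grid(dataset_id = c("A", "B"), n0 = c(20L, 50L, 100L),
                      generator = "g1", series_id = 1:2, n_prime = c(10L, 40L),
                      stringsAsFactors = FALSE)
  grid$baseline_auc <- 0.6
  # dataset A improves at n0 = 20 and 50 only; B never improves
  grid$auc <- ifelse(grid$dataset_id == "A" & grid$n0 <= 50, 0.65, 0.55)
  grid$failed <- FALSE
  grid
}

toy_profiles <- function() {
  pr <- expand.grid(dataset_id = c("A", "B"), n0 = c(20L, 50L, 100L),
                    stringsAsFactors = FALSE)
  pr$degrees_of_freedom <- 5L
  pr$imbalance_factor <- 2
  pr$std_entropy <- 0.8
  pr$mi_cv <- 0.4
  pr$separability <- 0.9
  pr$baseline_auc <- 0.6
  pr$n_predictors <- 4L
  pr
}

test_that("benefit table grouping matches a hand evaluation", {
  tab <- build_benefit_table(toy_records(), toy_profiles())
  expect_equal(nrow(tab), 6L)  # 2 datasets x 3 n0 x 1 generator
  got <- tab$benefit[order(tab$dataset_id, tab$n0)]
  expect_equal(got, c(1L, 1L, 0L, 0L, 0L, 0L))
  expect_true(all(tabaug:::BENEFIT_COVARIATES %in% names(tab)))
})

test_that("benefit rules differ when only some runs beat the baseline", {
  recs <- toy_records()
  # one lucky run in a B group: any_run flips, best_mean (over series) does
  # not since the n'-level mean stays below baseline
  hit <- which(recs$dataset_id == "B" & recs$n0 == 20 & recs$series_id == 1 &
                 recs$n_prime == 10)
  recs$auc[hit] <- 0.70  # mean over the 2 series at n'=10: (0.70+0.55)/2
  tab_any <- build_benefit_table(recs, toy_profiles(), rule = "any_run")
  tab_best <- build_benefit_table(recs, toy_profiles(), rule = "best_mean")
  b20 <- function(t) t$benefit[t$dataset_id == "B" & t$n0 == 20]
  expect_equal(b20(tab_any), 1L)
  expect_equal(b20(tab_best), 1L)  # 0.625 > 0.6 still improves
  recs$auc[hit] <- 0.64            # mean 0.595 < 0.6 but single run above
  expect_equal(b20(build_benefit_table(recs, toy_profiles(), "any_run")), 1L)
  expect_equal(b20(build_benefit_table(recs, toy_profiles(), "best_mean")), 0L)
})

test_that("covariate standardization is exact and invertible", {
  tab <- build_benefit_table(toy_records(), toy_profiles())
  tab$n0 <- as.numeric(tab$n0)
  std <- standardize_covariates(tab, c("n0"))
  expect_equal(mean(std$n0), 0, tolerance = 1e-10)
  expect_equal(stats::sd(std$n0), 1, tolerance = 1e-10)
  sc <- attr(std, "scaling")$n0
  expect_equal(std$n0 * sc["sd"] + sc["mean"], tab$n0,
               ignore_attr = TRUE)
  expect_warning(standardize_covariates(tab, c("imbalance_factor")),
                 "zero-variance")
})

simulate_glmm_table <- function(n = 2000, n_clusters = 20, sd_u = 0.5,
                                beta = c(-1.5, 0.5), seed = 1) {
  set.seed(seed)
  cl <- sample(n_clusters, n, TRUE)
  u <- rnorm(n_clusters, 0, sd_u)
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta <- -0.2 + beta[1] * x1 + beta[2] * x2 + u[cl]
  data.frame(dataset_id = paste0("c", cl), generator = "g", n0 = 1,
             x1 = x1, x2 = x2, benefit = rbinom(n, 1, plogis(eta)))
}

test_that("with no cluster variance the GLMM matches plain logistic", {
  tab <- simulate_glmm_table(sd_u = 0, seed = 3)
  fit <- fit_benefit_glmm(tab, covariates = c("x1", "x2"))
  glm_fit <- stats::glm(benefit ~ x1 + x2, data = tab,
                        family = stats::binomial())
  est <- coef(fit)
  ref <- stats::coef(glm_fit)
  se <- summary(glm_fit)$coefficients[, "Std. Error"]
  expect_true(all(abs(est - ref) < 2 * se))
})

test_that("odds ratios and CIs are exact transforms of the estimates", {
  tab <- simulate_glmm_table(seed = 5)
  fit <- fit_benefit_glmm(tab, covariates = c("x1", "x2"))
  for (block in list(fit$unstandardized, fit$standardized)) {
    expect_equal(block$odds_ratio, exp(block$estimate))
    expect_true(all(block$or_ci_lower < block$or_ci_upper))
    expect_equal(block$or_ci_lower,
                 exp(block$estimate - stats::qnorm(0.975) * block$se))
  }
  # Wald p-value ordering is preserved under standardization
  ord_u <- order(fit$unstandardized$p_value[-1])
  ord_s <- order(fit$standardized$p_value[-1])
  expect_equal(ord_u, ord_s)
})

test_that("constructed signal surfaces as the smallest p-values", {
  # benefit depends only on baseline_auc (negative) and dof (positive)
  set.seed(7)
  n <- 1200
  cl <- sample(12, n, TRUE)
  tab <- data.frame(
    dataset_id = paste0("d", cl),
    n0 = runif(n, 20, 1000),
    imbalance_factor = runif(n, 1, 5),
    degrees_of_freedom = runif(n, 2, 60),
    baseline_auc = runif(n, 0.5, 0.9),
    n_predictors = sample(4:12, n, TRUE),
    std_entropy = runif(n, 0.4, 1),
    mi_cv = runif(n, 0, 1.5),
    separability = runif(n, 0.3, 1.2))
  eta <- 6 - 12 * tab$baseline_auc + 0.08 * tab$degrees_of_freedom
  tab$benefit <- rbinom(n, 1, plogis(eta))
  fit <- fit_benefit_glmm(tab)
  p <- fit$standardized$p_value[-1]
  names(p) <- fit$standardized$term[-1]
  top2 <- names(sort(p))[1:2]
  expect_setequal(top2, c("baseline_auc", "degrees_of_freedom"))
})
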