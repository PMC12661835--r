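# The augmentation-benefit model: a per-{dataset, n0, generator} binary
# benefit table joined with the eight complexity characteristics, and a
# random-intercept logistic regression (dataset as the cluster) reported in
# unstandardized and standardized form with odds ratios and Wald 95% CIs.

BENEFIT_COVARIATES <- c("n0", "imbalance_factor", "degrees_of_freedom",
                        "baseline_auc", "n_predictors", "std_entropy",
                        "mi_cv", "separability")

#' Build the binary benefit table from simulation records
#'
#' For every {dataset, n0, generator} group the augmented ROC-AUCs are first
#' averaged over series per n' level; `benefit = 1` when the best such mean
#' (rule `"best_mean"`, the default), any single run (`"any_run"`), or the
#' overall mean (`"overall_mean"`) exceeds the group's baseline ROC-AUC.
#' The eight complexity covariates are joined by {dataset, n0}.
#'
#' @param records Simulation records from [run_grid()] (rows with
#'   `failed = TRUE` are ignored).
#' @param profiles Data frame of complexity profiles with `dataset_id` and
#'   `n0` keys (one row per base dataset), e.g. stacked
#'   [profile_dataset()] outputs.
#' @param rule Benefit rule, see above.
#' @return Data frame with `dataset_id, generator, n0`, the eight
#'   covariates and `benefit`.
#' @export
build_benefit_table <- function(records, profiles,
                                rule = c("best_mean", "any_run",
                                         "overall_mean")) {
  rule <- match.arg(rule)
  records <- records[!records$failed & !is.na(records$auc), , drop = FALSE]
  if (!nrow(records)) stop("no usable simulation records")
  key <- interaction(records$dataset_id, records$generator, records$n0,
                     drop = TRUE)
  groups <- split(records, key)
  rows <- lapply(groups, function(g) {
    baseline <- g$baseline_auc[1L]
    if (is.na(baseline)) stop("missing baseline for group ",
                              g$dataset_id[1L], "/", g$n0[1L])
    stat <- switch(rule,
      best_mean = max(tapply(g$auc, g$n_prime, mean)),
      any_run = max(g$auc),
      overall_mean = mean(g$auc))
    data.frame(dataset_id = g$dataset_id[1L], generator = g$generator[1L],
               n0 = g$n0[1L], benefit = as.integer(stat > baseline),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  m <- match(paste(tab$dataset_id, tab$n0),
             paste(profiles$dataset_id, profiles$n0))
  if (anyNA(m)) stop("profiles are missing for some {dataset, n0} groups")
  cov <- profiles[m, setdiff(BENEFIT_COVARIATES, "n0"), drop = FALSE]
  out <- cbind(tab[c("dataset_id", "generator", "n0")], cov,
               benefit = tab$benefit)
  rownames(out) <- NULL
  out
}

#' Standardize the benefit-model covariates
#'
#' Centers and scales each covariate column to unit sample SD; the scaling
#' state is attached as attribute `"scaling"` so estimates can be mapped
#' back. Zero-variance covariates are dropped with a warning.
#'
#' @param table A benefit table from [build_benefit_table()].
#' @param covariates Columns to standardize (default the eight
#'   characteristics).
#' @return The table with standardized covariates.
#' @export
standardize_covariates <- function(table, covariates = BENEFIT_COVARIATES) {
  covariates <- intersect(covariates, names(table))
  scaling <- list()
  for (nm in covariates) {
    mu <- mean(table[[nm]]); sdv <- stats::sd(table[[nm]])
    if (!is.finite(sdv) || sdv == 0) {
      warning("dropping zero-variance covariate '", nm, "'")
      table[[nm]] <- NULL
      next
    }
    scaling[[nm]] <- c(mean = mu, sd = sdv)
    table[[nm]] <- (table[[nm]] - mu) / sdv
  }
  attr(table, "scaling") <- scaling
  table
}

glmm_coef_table <- function(fit) {
  sm <- summary(fit)$coefficients
  z975 <- stats::qnorm(0.975)
  data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
             se = sm[, "Std. Error"], z = sm[, "z value"],
             p_value = sm[, "Pr(>|z|)"],
             odds_ratio = exp(sm[, "Estimate"]),
             or_ci_lower = exp(sm[, "Estimate"] - z975 * sm[, "Std. Error"]),
             or_ci_upper = exp(sm[, "Estimate"] + z975 * sm[, "Std. Error"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the random-intercept logistic model of augmentation benefit
#'
#' `benefit ~ covariates + (1 | dataset_id)` with a logit link, estimated by
#' Laplace-approximate maximum likelihood (lme4). Both the unstandardized
#' fit and a fit on standardized covariates are returned, each with Wald
#' p-values, odds ratios and 95% CIs.
#'
#' @param table A benefit table from [build_benefit_table()] (>= 2 dataset
#'   clusters, both benefit outcomes present).
#' @param covariates Fixed-effect columns (default the eight
#'   characteristics).
#' @param include_standardized Also fit the standardized variant
#'   (default TRUE).
#' @return An object of class `tabaug_benefit_fit` with elements
#'   `unstandardized`, `standardized` (coefficient tables),
#'   `random_intercept_variance`, `converged` and the underlying lme4 fits.
#' @export
fit_benefit_glmm <- function(table, covariates = BENEFIT_COVARIATES,
                             include_standardized = TRUE) {
  covariates <- intersect(covariates, names(table))
  if (length(unique(table$dataset_id)) < 2L)
    stop("need >= 2 dataset clusters")
  if (length(unique(table$benefit)) < 2L)
    stop("benefit outcome is constant")
  fml <- stats::as.formula(paste("benefit ~",
                                 paste(covariates, collapse = " + "),
                                 "+ (1 | dataset_id)"))
  fit_one <- function(dat) {
    warns <- character()
    fit <- withCallingHandlers(
      lme4::glmer(fml, data = dat, family = stats::binomial()),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    list(fit = fit, warnings = warns)
  }
  raw <- fit_one(table)
  if (include_standardized) {
    std_tab <- standardize_covariates(table, covariates)
    std <- fit_one(std_tab)
  } else {
    std_tab <- NULL
    std <- raw
  }
  vc <- lme4::VarCorr(raw$fit)
  structure(list(
    unstandardized = glmm_coef_table(raw$fit),
    standardized = glmm_coef_table(std$fit),
    random_intercept_variance = as.numeric(vc$dataset_id[1L, 1L]),
    converged = length(raw$warnings) == 0L,
    warnings = unique(c(raw$warnings, std$warnings)),
    scaling = if (!is.null(std_tab)) attr(std_tab, "scaling") else NULL,
    fits = list(unstandardized = raw$fit, standardized = std$fit)),
    class = "tabaug_benefit_fit")
}

#' @export
print.tabaug_benefit_fit <- function(x, ...) {
  cat("<tabaug_benefit_fit> random-intercept logistic model of augmentation benefit\n")
  cat(sprintf("  random intercept variance: %.4f%s\n",
              x$random_intercept_variance,
              if (!x$converged) "  (fit flagged: see $warnings)" else ""))
  tab <- x$standardized
  cat("  standardized fixed effects:\n")
  for (i in seq_len(nrow(tab)))
    cat(sprintf("    %-20s %8.3f  (p = %.4g)\n", tab$term[i],
                tab$estimate[i], tab$p_value[i]))
  invisible(x)
}

#' @export
summary.tabaug_benefit_fit <- function(object, ...) {
  list(unstandardized = object$unstandardized,
       standardized = object$standardized,
       random_intercept_variance = object$random_intercept_variance,
       converged = object$converged)
}

#' @export
coef.tabaug_benefit_fit <- function(object,
                                    which = c("unstandardized",
                                              "standardized"), ...) {
  which <- match.arg(which)
  stats::setNames(object[[which]]$estimate, object[[which]]$term)
}
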