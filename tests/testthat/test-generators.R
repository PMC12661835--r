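test_that("bootstrap samples whole observed rows with correct frequencies", {
  set.seed(4)
  base <- dataset(data.frame(age = 1:10, sex = rep(c("M", "F"), 5),
                             outcome = rep(c("0", "1"), each = 5),
                             stringsAsFactors = FALSE),
                  toy_schema(), id = "b")
  g <- fit_bootstrap(base)
  s <- sample_synth(g, 100, seed = 1)
  key <- function(d) paste(d$age, d$sex, d$outcome)
  expect_true(all(key(s$data) %in% key(base$data)))

  one <- subset_rows(base, 1L)
  g1 <- fit_bootstrap(one)
  s1 <- sample_synth(g1, 20, seed = 2)
  expect_true(all(key(s1$data) == key(one$data)))

  # multinomial frequency check: 10 distinct rows, m = 10000
  s2 <- sample_synth(g, 10000, seed = 3)
  freq <- table(factor(s2$data$age, levels = 1:10)) / 10000
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_true(all(abs(freq - 0.1) < 3 * se))
})

test_that("sequential trees reproduce marginals and deterministic structure", {
  # all rows identical -> every synthetic row identical
  const <- dataset(data.frame(age = rep(1.5, 20), sex = rep("M", 20),
                              outcome = rep(c("0", "1"), 10),
                              stringsAsFactors = FALSE),
                   toy_schema(), id = "const")
  g <- fit_seq_trees(const, min_leaf = 2)
  s <- sample_synth(g, 50, seed = 1)
  expect_true(all(s$data$age == 1.5))
  expect_true(all(s$data$sex == "M"))

  # single binary variable marginal within 3*SE
  bp <- binary_pair_dataset(2000, p = 0.3, seed = 2)
  g2 <- fit_seq_trees(bp)
  s2 <- sample_synth(g2, 10000, seed = 3)
  phat_x <- mean(s2$data$x == "1")
  p_train <- mean(bp$data$x == "1")
  expect_lt(abs(phat_x - p_train), 3 * sqrt(0.3 * 0.7 / 10000) + 0.01)

  # deterministic copy Y = X is preserved exactly (pure leaves)
  cp <- binary_pair_dataset(400, p = 0.4, copy = TRUE, seed = 5)
  g3 <- fit_seq_trees(cp, min_leaf = 5)
  s3 <- sample_synth(g3, 1000, seed = 7)
  expect_true(all(as.character(s3$data$x) == as.character(s3$data$outcome)))
})

test_that("generator sampling contract: determinism, m >= 1, level closure", {
  base <- small_population(300, seed = 9)
  for (fit_fun in list(fit_bootstrap, fit_seq_trees, fit_bayes_net)) {
    g <- fit_fun(base)
    expect_error(sample_synth(g, 0, seed = 1), "m must be")
    a <- sample_synth(g, 40, seed = 11)
    b <- sample_synth(g, 40, seed = 11)
    expect_identical(a$data, b$data)
    expect_equal(nrow(a$data), 40L)
    for (nm in schema_names(base$schema)) {
      if (is.factor(base$data[[nm]]))
        expect_true(all(as.character(a$data[[nm]]) %in%
                          unique(as.character(base$data[[nm]]))))
    }
  }
})

test_that("hill-climb BIC recovers independence and deterministic coupling", {
  # hand BIC oracle for a candidate arc between two binaries
  bic_empty_vs_arc <- function(x, y) {
    n <- length(x)
    ll_marg <- function(v) {
      cnt <- table(v)
      sum(cnt * log(cnt / n))
    }
    ll_cond <- function(child, parent) {
      tab <- table(parent, child)
      rs <- rowSums(tab)
      sum(tab[tab > 0] * log((tab / rs)[tab > 0]))
    }
    empty <- ll_marg(x) + ll_marg(y) - 0.5 * log(n) * (1 + 1)
    arc <- ll_marg(x) + ll_cond(y, x) - 0.5 * log(n) * (1 + 2)
    c(empty = empty, arc = arc)
  }

  ind <- binary_pair_dataset(5000, p = 0.5, copy = FALSE, seed = 3)
  g <- fit_bayes_net(ind)
  n_arcs <- sum(lengths(g$state$dag$parents))
  oracle <- bic_empty_vs_arc(ind$data$x, ind$data$outcome)
  expect_gt(oracle["empty"], oracle["arc"])  # independence favored
  expect_equal(n_arcs, 0L)

  dep <- binary_pair_dataset(5000, p = 0.4, copy = TRUE, seed = 4)
  g2 <- fit_bayes_net(dep)
  oracle2 <- bic_empty_vs_arc(dep$data$x, dep$data$outcome)
  expect_gt(oracle2["arc"], oracle2["empty"])  # coupling favored
  expect_equal(sum(lengths(g2$state$dag$parents)), 1L)
})

test_that("bayes net invariants: acyclic graph, normalized CPT rows", {
  base <- small_population(500, seed = 17)
  g <- fit_bayes_net(base)
  expect_silent(tabaug:::topological_order(g$state$dag$parents))
  for (cpt in g$state$cpts)
    expect_true(all(abs(rowSums(cpt$probs) - 1) < 1e-9))
})

test_that("bayes net sampling matches the fitted joint for independent vars", {
  ind <- binary_pair_dataset(5000, p = 0.5, copy = FALSE, seed = 8)
  g <- fit_bayes_net(ind)
  s <- sample_synth(g, 20000, seed = 9)
  px <- mean(ind$data$x == "1"); py <- mean(ind$data$outcome == "1")
  pj <- mean(s$data$x == "1" & s$data$outcome == "1")
  se <- sqrt(px * py * (1 - px * py) / 20000)
  expect_lt(abs(pj - px * py), 3 * se + 0.01)
})

test_that("SEQ and BN samples reproduce a 5-level categorical marginal", {
  set.seed(31)
  probs <- c(0.35, 0.25, 0.2, 0.15, 0.05)
  lv <- paste0("L", 1:5)
  df <- data.frame(g = sample(lv, 3000, TRUE, prob = probs),
                   outcome = sample(c("0", "1"), 3000, TRUE),
                   stringsAsFactors = FALSE)
  ds <- dataset(df, schema(var_spec("g", "categorical", levels = lv),
                           var_spec("outcome", "categorical",
                                    levels = c("0", "1"), role = "outcome")),
                id = "lv5")
  p_train <- prop.table(table(factor(df$g, levels = lv)))
  for (g in list(fit_seq_trees(ds), fit_bayes_net(ds))) {
    s <- sample_synth(g, 20000, seed = 13)
    obs <- table(factor(as.character(s$data$g), levels = lv))
    chi <- suppressWarnings(stats::chisq.test(obs, p = as.numeric(p_train)))
    expect_gt(chi$p.value, 0.01)
  }
})

test_that("augment concatenates base verbatim plus n_prime synthetic rows", {
  base <- small_population(50, seed = 23)
  g <- fit_bootstrap(base)
  aug <- augment(base, g, 25, seed = 2)
  expect_equal(nrow(aug$data), 75L)
  expect_identical(aug$data[1:50, ], local({
    d <- base$data; rownames(d) <- NULL; d
  }))
  expect_error(augment(base, g, 0), "n_prime")
})

test_that("the external adapter contract round-trips through a command", {
  skip_on_os("windows")
  base <- toy_dataset(20, seed = 6)
  helper <- withr::local_tempfile(fileext = ".R")
  writeLines(c(
    'args <- commandArgs(trailingOnly = TRUE)',
    'df <- read.csv(args[1], colClasses = "character")',
    'set.seed(as.integer(args[4]))',
    'idx <- sample.int(nrow(df), as.integer(args[3]), replace = TRUE)',
    'write.csv(df[idx, , drop = FALSE], args[5], row.names = FALSE)'
  ), helper)
  g <- fit_adapter(base, c(file.path(R.home("bin"), "Rscript"), helper))
  s <- sample_synth(g, 15, seed = 3)
  expect_equal(nrow(s$data), 15L)
  expect_true(all(as.character(s$data$sex) %in%
                    as.character(base$data$sex)))
})
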