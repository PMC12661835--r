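test_that("imbalance factor matches hand values and symmetry", {
  expect_equal(imbalance_factor(rep(c(0, 1), 50)), 1)
  expect_equal(imbalance_factor(c(rep(1, 20), rep(0, 80))), 4)
  expect_equal(imbalance_factor(c(rep(1, 80), rep(0, 20))), 4)
  expect_error(imbalance_factor(rep(1, 10)), "both classes")
})

test_that("degrees of freedom sum 1 per numeric and k-1 per categorical", {
  s1 <- schema(var_spec("a", "numeric"),
               var_spec("y", "categorical", levels = c("0", "1"),
                        role = "outcome"))
  expect_equal(degrees_of_freedom(s1), 1L)
  s2 <- schema(var_spec("g", "categorical", levels = paste0("l", 1:5)),
               var_spec("y", "categorical", levels = c("0", "1"),
                        role = "outcome"))
  expect_equal(degrees_of_freedom(s2), 4L)
  s3 <- schema(var_spec("a", "numeric"), var_spec("b", "numeric"),
               var_spec("g", "categorical", levels = paste0("l", 1:3)),
               var_spec("y", "categorical", levels = c("0", "1"),
                        role = "outcome"))
  expect_equal(degrees_of_freedom(s3), 4L)
})

test_that("standardized entropy: uniform 1, constant 0, hand value", {
  lv <- paste0("l", 1:4)
  ds <- dataset(data.frame(g = rep(lv, 25),
                           outcome = rep(c("0", "1"), 50),
                           stringsAsFactors = FALSE),
                schema(var_spec("g", "categorical", levels = lv),
                       var_spec("outcome", "categorical", levels = c("0", "1"),
                                role = "outcome")))
  expect_equal(standardized_entropy(ds), 1)

  dsc <- dataset(data.frame(g = rep("l1", 40),
                            outcome = rep(c("0", "1"), 20),
                            stringsAsFactors = FALSE),
                 schema(var_spec("g", "categorical", levels = lv),
                        var_spec("outcome", "categorical",
                                 levels = c("0", "1"), role = "outcome")))
  expect_equal(standardized_entropy(dsc), 0)

  # binary with p = 0.25: H/log(2) = 0.8113
  dsb <- dataset(data.frame(g = c(rep("l1", 25), rep("l2", 75)),
                            outcome = rep(c("0", "1"), 50),
                            stringsAsFactors = FALSE),
                 schema(var_spec("g", "categorical", levels = lv),
                        var_spec("outcome", "categorical",
                                 levels = c("0", "1"), role = "outcome")))
  expect_equal(standardized_entropy(dsb),
               (-0.25 * log(0.25) - 0.75 * log(0.75)) / log(2),
               tolerance = 1e-12)
})

test_that("MI coefficient of variation uses the sample SD and guards", {
  # direct check of the CV arithmetic on a constructed pair set
  expect_equal(stats::sd(c(0.1, 0.3)) / mean(c(0.1, 0.3)),
               0.1414214 / 0.2, tolerance = 1e-5)

  # identical pairwise MI -> CV 0: three mutually independent uniform vars
  # give MI ~ 0 for all pairs, so test via a perfectly symmetric fixture
  lv <- c("a", "b")
  df <- expand.grid(x = lv, y = lv, z = lv, stringsAsFactors = FALSE)
  df <- df[rep(seq_len(nrow(df)), 10), ]
  df$outcome <- rep(c("0", "1"), length.out = nrow(df))
  ds <- dataset(df, schema(var_spec("x", "categorical", levels = lv),
                           var_spec("y", "categorical", levels = lv),
                           var_spec("z", "categorical", levels = lv),
                           var_spec("outcome", "categorical",
                                    levels = c("0", "1"), role = "outcome")))
  expect_warning(cv <- mutual_info_cv(ds), "zero")
  expect_equal(cv, 0)

  one <- dataset(data.frame(x = rep(lv, 10),
                            outcome = rep(c("0", "1"), 10),
                            stringsAsFactors = FALSE),
                 schema(var_spec("x", "categorical", levels = lv),
                        var_spec("outcome", "categorical", levels = c("0", "1"),
                                 role = "outcome")))
  expect_error(mutual_info_cv(one), ">= 2 predictors")
})

test_that("Gower distance hand values and cross-check against daisy", {
  sch <- schema(var_spec("a", "numeric"),
                var_spec("g", "categorical", levels = c("x", "y")),
                var_spec("outcome", "categorical", levels = c("0", "1"),
                         role = "outcome"))
  r1 <- list(a = 5, g = "x"); r2 <- list(a = 10, g = "y")
  expect_equal(gower_distance(r1, r1, sch, ranges = list(a = 10)), 0)
  expect_equal(gower_distance(r1, r2, sch, ranges = list(a = 10)),
               (0.5 + 1) / 2)
  # all-categorical, all differing -> 1
  sch2 <- schema(var_spec("g", "categorical", levels = c("x", "y")),
                 var_spec("h", "categorical", levels = c("u", "v")),
                 var_spec("outcome", "categorical", levels = c("0", "1"),
                          role = "outcome"))
  expect_equal(gower_distance(list(g = "x", h = "u"), list(g = "y", h = "v"),
                              sch2, ranges = list()), 1)

  skip_if_not_installed("cluster")
  set.seed(2)
  df <- data.frame(a = runif(15), g = sample(c("x", "y"), 15, TRUE),
                   outcome = sample(c("0", "1"), 15, TRUE),
                   stringsAsFactors = FALSE)
  ds <- dataset(df, sch)
  G <- tabaug:::gower_matrix(ds)
  D <- as.matrix(cluster::daisy(
    data.frame(a = df$a, g = factor(df$g)), metric = "gower"))
  expect_equal(unname(G), unname(D), tolerance = 1e-10)
})

test_that("separability matches the brute-force 1-D example", {
  # class0 at {0, 0.1}, class1 at {1.0, 1.1}; brute force over all pairwise
  # normalized distances: intra NN = 0.1/1.1 for every record, inter NN =
  # {1.0, 0.9, 0.9, 1.0}/1.1, so the ratio of means is 0.1/0.95
  ds <- dataset(data.frame(x = c(0, 0.1, 1.0, 1.1),
                           outcome = c("neg", "neg", "pos", "pos"),
                           stringsAsFactors = FALSE),
                schema(var_spec("x", "numeric"),
                       var_spec("outcome", "categorical",
                                levels = c("neg", "pos"), role = "outcome")))
  expect_equal(separability(ds), 0.1 / 0.95, tolerance = 1e-12)

  # interleaved identical geometry -> ratio ~ 1
  ds2 <- dataset(data.frame(x = seq(0, 3.5, by = 0.5),
                            outcome = rep(c("neg", "pos"), 4),
                            stringsAsFactors = FALSE),
                 schema(var_spec("x", "numeric"),
                        var_spec("outcome", "categorical",
                                 levels = c("neg", "pos"), role = "outcome")))
  expect_equal(separability(ds2), 2, tolerance = 1e-9)
  # (nearest same-class neighbor is 1.0 away, other-class 0.5 away)

  one_class <- dataset(data.frame(x = 1:4,
                                  outcome = rep("pos", 4),
                                  stringsAsFactors = FALSE),
                       schema(var_spec("x", "numeric"),
                              var_spec("outcome", "categorical",
                                       levels = c("neg", "pos"),
                                       role = "outcome")))
  expect_error(separability(one_class), "both classes")
})

test_that("separability falls as class centroids separate", {
  vals <- vapply(c(0.5, 2, 5), function(sp)
    separability(two_cluster_dataset(40, spacing = sp, seed = 4)),
    numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("characteristics are invariant to row order and relabeling", {
  ds <- small_population(400, seed = 31)
  set.seed(9)
  perm <- sample.int(nrow(ds$data))
  dsp <- subset_rows(ds, perm)
  expect_equal(standardized_entropy(ds), standardized_entropy(dsp))
  expect_equal(mutual_info_cv(ds), mutual_info_cv(dsp))
  expect_equal(imbalance_factor(ds), imbalance_factor(dsp))
  expect_equal(separability(ds), separability(dsp))

  # relabel categorical levels bijectively: entropy unchanged
  ds2 <- ds
  lv <- levels(ds2$data$cat2)
  relab <- setNames(rev(lv), lv)
  ds2$data$cat2 <- factor(unname(relab[as.character(ds2$data$cat2)]),
                          levels = lv)
  expect_equal(standardized_entropy(ds), standardized_entropy(ds2))
})

test_that("profile assembles all eight characteristics reproducibly", {
  pop <- small_population(2000, seed = 41)
  sp <- split_population(pop, 0.7, seed = 2)
  base <- draw_base(sp$train, 120, seed = 3)
  p1 <- profile_dataset(base, sp$test, fast_settings(seed = 5))
  p2 <- profile_dataset(base, sp$test, fast_settings(seed = 5))
  expect_identical(p1, p2)
  expect_equal(p1$n0, 120L)
  expect_equal(p1$n_predictors, 4L)
  expect_true(all(is.finite(unlist(p1[tabaug:::BENEFIT_COVARIATES]))))
})
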