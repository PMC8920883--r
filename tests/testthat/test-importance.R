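# small planted-signal cohort for forest tests: one strong binary predictor
# among noise factors
forest_cohort <- function(n = 2000, seed = 1, p_base = 0.2, or = 5) {
  cat_f <- factor_catalog(c(
    list(fct_def("signal", c("absent", "present"))),
    lapply(1:6, function(i) fct_def(sprintf("noise%02d", i),
                                    c("a", "b", "c")))))
  simulate_cohort(sim_config(
    cat_f, n = n, seed = seed,
    outcomes = "disease", baseline_prev = c(disease = p_base),
    effects = list(planted_effect("disease", "signal",
                                  main = c(present = log(or))))))
}

test_that("bias-corrected Cramer's V flags duplicated factors only", {
  set.seed(5)
  n <- 2000
  df <- data.frame(subject_id = as.character(1:n),
                   exposure = sample(c("index", "reference"), n, TRUE),
                   disease = sample(c("yes", "no"), n, TRUE),
                   f1 = sample(letters[1:3], n, TRUE),
                   f4 = sample(letters[1:4], n, TRUE))
  df$f2 <- df$f1            # exact duplicate
  df$f3 <- df$f1            # triple
  cat_f <- factor_catalog(
    fct_def("f1", letters[1:3]), fct_def("f2", letters[1:3]),
    fct_def("f3", letters[1:3]), fct_def("f4", letters[1:4]))
  co <- cohort_table(df, cat_f, index_level = "index",
                     reference_level = "reference", outcomes = "disease",
                     strict = TRUE)
  expect_equal(cramers_v(df$f1, df$f2), 1, tolerance = 1e-12)
  flt <- correlation_filter(co, threshold = 0.9)
  # three mutual duplicates: two dropped, one retained; f4 independent
  expect_identical(flt$retained, c("f1", "f4"))
  expect_identical(sort(flt$dropped$factor), c("f2", "f3"))
  # independent factors stay below the threshold
  expect_lt(flt$matrix["f1", "f4"], 0.9)
  expect_identical(dim(flt$matrix), c(4L, 4L))
})

test_that("the OOB grid search is deterministic and picks the minimum", {
  co <- forest_cohort(n = 800, seed = 3)
  cfg <- forest_config(n_trees = 60, nodesize = c(5, 10), nsplit = 2,
                       mtry = c(2, 4), seed = 99)
  f1 <- fit_forest(co, "disease", cfg)
  f2 <- fit_forest(co, "disease", cfg)
  expect_identical(f1$oob_error, f2$oob_error)
  expect_identical(f1$grid$oob_error, f2$grid$oob_error)
  expect_true(all(f1$oob_error <= f1$grid$oob_error))
  expect_identical(length(f1$train_idx), 640L)
  # single-class outcome is rejected
  df <- as.data.frame(co); df$disease <- "no"
  co_flat <- cohort_table(df, attr(co, "catalog"), index_level = "index",
                          reference_level = "reference", outcomes = "disease",
                          strict = TRUE)
  expect_error(fit_forest(co_flat, "disease", cfg), "single class")
})

test_that("OOB error tracks the learnability of the outcome", {
  # pure-noise outcome: error near the 0.5 coin flip
  cat_n <- factor_catalog(lapply(1:5, function(i)
    fct_def(sprintf("n%02d", i), c("a", "b"))))
  co_noise <- simulate_cohort(sim_config(cat_n, n = 1500, seed = 7,
                                         outcomes = "disease",
                                         baseline_prev = c(disease = 0.5)))
  f_noise <- fit_forest(co_noise, "disease",
                        forest_config(n_trees = 80, nodesize = 10,
                                      nsplit = 2, mtry = 3, seed = 1))
  expect_gte(f_noise$oob_error, 0.45)
  expect_lte(f_noise$oob_error, 0.55)

  # outcome equal to one factor's level indicator: near-perfect recovery
  df <- as.data.frame(co_noise)
  df$disease <- ifelse(df$n01 == "a", "yes", "no")
  co_det <- cohort_table(df, cat_n, index_level = "index",
                         reference_level = "reference", outcomes = "disease",
                         strict = TRUE)
  f_det <- fit_forest(co_det, "disease",
                      forest_config(n_trees = 80, nodesize = 10, nsplit = 2,
                                    mtry = 3, seed = 1))
  expect_lte(f_det$oob_error, 0.02)
  expect_lte(f_det$test_error, 0.02)
})

test_that("VIMP and minimal depth both surface the planted predictor", {
  co <- forest_cohort(n = 3000, seed = 11)
  ffit <- fit_forest(co, "disease",
                     forest_config(n_trees = 120, nodesize = 10, nsplit = 2,
                                   mtry = 3, seed = 5))
  v <- vimp(ffit)
  expect_identical(names(v)[1], "signal")
  expect_gt(v[["signal"]], 0)
  md <- minimal_depth(ffit)
  expect_identical(names(md$depth)[1], "signal")
  expect_true("signal" %in% md$selected)
  expect_gt(md$threshold, md$depth[["signal"]])
  tab <- importance_table(ffit)
  expect_identical(tab$factor[1], "signal")
  expect_true(tab$selected[1])
})

test_that("VIMP estimates concentrate as the ensemble grows", {
  # fixed train/test split, independent tree/permutation seeds: the VIMP
  # difference between two forests shrinks with the number of trees
  co <- forest_cohort(n = 1500, seed = 8)
  vdiff <- function(nt, s1, s2) {
    f <- function(s) vimp(fit_forest(co, "disease",
      forest_config(n_trees = nt, nodesize = 10, nsplit = 2, mtry = 3,
                    seed = s, split_seed = 77)))
    v1 <- f(s1); v2 <- f(s2)
    mean(abs(v1[names(v2)] - v2))
  }
  pairs <- list(c(1, 2), c(3, 4), c(5, 6))
  d_small <- mean(vapply(pairs, function(p) vdiff(100, p[1], p[2]), numeric(1)))
  d_large <- mean(vapply(pairs, function(p) vdiff(1000, p[1], p[2]), numeric(1)))
  expect_lt(d_large, d_small)
})

test_that("a constant factor is never split on: zero VIMP, max depth", {
  co <- forest_cohort(n = 800, seed = 2)
  df <- as.data.frame(co)
  df$flat <- "only"
  cat_plus <- factor_catalog(c(unclass(attr(co, "catalog")),
                               list(flat = fct_def("flat", "only"))))
  co2 <- cohort_table(df, cat_plus, index_level = "index",
                      reference_level = "reference", outcomes = "disease",
                      strict = TRUE)
  ffit <- fit_forest(co2, "disease",
                     forest_config(n_trees = 50, nodesize = 10, nsplit = 2,
                                   mtry = 8, seed = 3))
  expect_identical(unname(vimp(ffit)[["flat"]]), 0)
  md <- minimal_depth(ffit)
  expect_identical(unname(which.max(md$depth)), length(md$depth))
  expect_identical(names(md$depth)[length(md$depth)], "flat")
})
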