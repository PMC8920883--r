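test_that("worked-example 2x2 tables reproduce the printed ORs and CIs", {
  co <- table1_cohort()
  # whole-cohort crosstab against the common no-disease control group
  tab <- crosstab(co, "asthma", control = "neither")
  expect_identical(unlist(tab[c("a", "b", "c", "d")]),
                   c(a = 35L, b = 43L, c = 1361L, d = 2814L))
  cases <- list(asthma = c(1.68, 1.07, 2.64),
                rhinitis = c(0.84, 0.66, 1.06),
                both = c(1.03, 0.63, 1.69))
  for (oc in names(cases)) {
    tab <- crosstab(co, oc)
    est <- odds_ratio(tab)
    ci <- wald_ci(tab)
    expect_equal(round(est$point, 2), cases[[oc]][1])
    expect_equal(round(unname(ci["low"]), 2), cases[[oc]][2])
    expect_equal(round(unname(ci["high"]), 2), cases[[oc]][3])
    # the iterative logistic route agrees
    lg <- logistic_or(co, oc)
    expect_equal(lg$point, est$point, tolerance = 1e-8)
    expect_equal(round(lg$ci_low, 2), cases[[oc]][2])
  }
})

test_that("Wald CI matches the closed form on a hand-computed table", {
  # all cells 100: SE = sqrt(4/100) = 0.2, OR = 1
  ci <- wald_ci(two_by_two(100, 100, 100, 100))
  z <- qnorm(0.975)
  expect_equal(unname(ci["low"]), exp(-z * 0.2), tolerance = 1e-12)
  expect_equal(unname(ci["high"]), exp(z * 0.2), tolerance = 1e-12)
  expect_equal(odds_ratio(two_by_two(10, 10, 10, 10))$point, 1)
})

test_that("degenerate tables are encoded, not raised", {
  expect_identical(odds_ratio(two_by_two(5, 0, 3, 4))$point, Inf)
  expect_identical(odds_ratio(two_by_two(5, 2, 0, 4))$point, Inf)
  expect_identical(odds_ratio(two_by_two(0, 2, 3, 4))$point, 0)
  expect_identical(odds_ratio(two_by_two(5, 2, 3, 0))$point, 0)
  expect_true(is.nan(odds_ratio(two_by_two(0, 0, 3, 4))$point))
  ci <- wald_ci(two_by_two(5, 0, 3, 4))
  expect_true(all(is.na(ci)))
  expect_true(attr(ci, "undefined"))
})

test_that("swapping exposure arms inverts the odds ratio and its CI", {
  set.seed(42)
  for (i in 1:25) {
    cells <- sample(1:400, 4)
    t1 <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    t2 <- two_by_two(cells[2], cells[1], cells[4], cells[3])
    expect_equal(odds_ratio(t1)$point, 1 / odds_ratio(t2)$point,
                 tolerance = 1e-12)
    c1 <- wald_ci(t1); c2 <- wald_ci(t2)
    expect_equal(unname(c1["low"]), 1 / unname(c2["high"]), tolerance = 1e-12)
  }
})

test_that("logistic and closed-form odds ratios agree on random tables", {
  set.seed(7)
  co <- table1_cohort()
  # quick oracle-equivalence sample (the full 200-table sweep runs in the
  # acceptance suite)
  for (i in 1:20) {
    cells <- sample(1:500, 4)
    tab <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    dat <- data.frame(
      subject_id = as.character(seq_len(sum(cells))),
      exposure = rep(c("index", "reference", "index", "reference"), cells),
      asthma = rep(c("yes", "yes", "no", "no"), cells),
      sex = "male")
    cot <- cohort_table(dat, factor_catalog(fct_def("sex", "male")),
                        index_level = "index", reference_level = "reference",
                        outcomes = "asthma", strict = TRUE)
    lg <- logistic_or(cot, "asthma", control = "all")
    cf <- odds_ratio(tab)$point
    expect_lt(abs(lg$point - cf) / cf, 1e-6)
  }
  # separation: a zero cell falls back to the closed-form encoding
  dat <- data.frame(subject_id = as.character(1:40),
                    exposure = rep(c("index", "reference"), each = 20),
                    asthma = rep(c("yes", "no"), c(20, 20)),
                    sex = "male")
  cot <- cohort_table(dat, factor_catalog(fct_def("sex", "male")),
                      index_level = "index", reference_level = "reference",
                      outcomes = "asthma", strict = TRUE)
  lg <- logistic_or(cot, "asthma", control = "all")
  expect_true("separation" %in% lg$flags)
  expect_identical(lg$point, Inf)
})

test_that("crude proportions reproduce the printed prevalences", {
  co <- table1_cohort()
  # of all 4686 subjects: 78 asthma-only, 361 rhinitis-only
  expect_equal(round(100 * crude_proportion(co, "asthma", control = "all")$point, 1),
               1.7)
  expect_equal(round(100 * crude_proportion(co, "rhinitis", control = "all")$point, 1),
               7.7)
  # against the common control group (the screen's universe)
  expect_equal(round(100 * crude_proportion(co, "asthma")$point, 1), 1.8)
  expect_equal(round(100 * crude_proportion(co, "rhinitis")$point, 1), 8.0)
  expect_equal(crude_proportion(co, "asthma")$n, 78 + 4175)
})

test_that("display truncation clamps without touching the stored point", {
  cfg <- trunc_config()
  e1 <- truncate_display(odds_ratio(two_by_two(10, 10, 10, 78)), cfg)
  expect_equal(e1$display, 7.8, tolerance = 1e-12)
  expect_false("truncated" %in% e1$flags)
  e2 <- truncate_display(odds_ratio(two_by_two(400, 10, 10, 100)), cfg)
  expect_identical(e2$display, 15)
  expect_true("truncated" %in% e2$flags)
  expect_equal(e2$point, 400, tolerance = 1e-12)  # stored point untouched
  expect_identical(truncate_display(e2, cfg)$display, e2$display) # idempotent
  # infinite -> upper bound, zero/undefined -> lower bound, for display only
  expect_identical(truncate_display(odds_ratio(two_by_two(5, 0, 3, 4)), cfg)$display, 15)
  expect_identical(truncate_display(odds_ratio(two_by_two(0, 5, 3, 4)), cfg)$display, 0.3)
  expect_identical(truncate_display(c(0.1, 2, Inf, NaN, 40), cfg),
                   c(0.3, 2, 15, 0.3, 15))
  expect_error(trunc_config(10, 3))
})

test_that("Wald CIs for a null odds ratio cover 1 at the nominal rate", {
  # true OR = 1, 500 per arm, 1000 replicates: coverage must sit near 95%
  set.seed(2024)
  covered <- logical(1000)
  for (r in 1:1000) {
    a <- rbinom(1, 500, 0.2); b <- rbinom(1, 500, 0.2)
    ci <- wald_ci(two_by_two(a, b, 500 - a, 500 - b))
    covered[r] <- !anyNA(ci) && ci["low"] <= 1 && 1 <= ci["high"]
  }
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})
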