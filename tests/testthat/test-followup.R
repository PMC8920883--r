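# simulated follow-up cohort: one truly associated factor among decoys
followup_cohort <- function(n = 5000, seed = 1, beta = log(2.5)) {
  cat_f <- factor_catalog(
    fct_def("true_f", c("ref", "hit")),
    fct_def("decoy1", c("a", "b")),
    fct_def("decoy2", c("a", "b", "c")))
  simulate_cohort(sim_config(
    cat_f, n = n, seed = seed, outcomes = "disease",
    baseline_prev = c(disease = 0.1),
    effects = list(planted_effect("disease", "true_f",
                                  main = c(hit = beta)))))
}

test_that("the intercept-only fit recovers the closed-form log odds", {
  co <- table1_cohort()
  sp <- model_spec("asthma", include_exposure = FALSE)
  fit <- fit_logistic(co, sp)
  # 78 cases vs 4175 no-disease controls
  expect_equal(fit$coef$estimate[1], log(78 / 4175), tolerance = 1e-8)
  expect_identical(fit$lr_df, 0L)
  expect_identical(fit$lr_p, 1)
  expect_equal(fit$lr_stat, 0, tolerance = 1e-10)
  # AIC identity for every reported fit
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 1, tolerance = 1e-10)
})

test_that("a single binary covariate reproduces the 2x2 odds ratio", {
  co <- table1_cohort()
  fit <- fit_logistic(co, model_spec("asthma"))
  cf <- odds_ratio(crosstab(co, "asthma"))$point
  i <- grep("exposure", fit$coef$term)
  expect_lt(abs(fit$coef$or[i] - cf) / cf, 1e-6)
  expect_equal(round(fit$coef$or[i], 2), 1.68)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * nrow(fit$coef), tolerance = 1e-10)
})

test_that("the LR test is invariant to reference-level recoding", {
  co <- followup_cohort(n = 3000, seed = 4)
  f1 <- fit_logistic(co, model_spec("disease", main = c("true_f", "decoy2")))
  f2 <- fit_logistic(co, model_spec("disease", main = c("true_f", "decoy2"),
                                    refs = list(true_f = "hit",
                                                decoy2 = "c")))
  expect_equal(f1$lr_stat, f2$lr_stat, tolerance = 1e-8)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-8)
  expect_identical(f1$lr_df, f2$lr_df)
  # rank deficiency names the aliased term
  df <- as.data.frame(co)
  df$dup <- df$true_f
  cat_plus <- factor_catalog(c(unclass(attr(co, "catalog")),
                               list(dup = fct_def("dup", c("ref", "hit")))))
  co2 <- cohort_table(df, cat_plus, index_level = "index",
                      reference_level = "reference", outcomes = "disease",
                      strict = TRUE)
  expect_error(fit_logistic(co2, model_spec("disease", main = c("true_f", "dup"))),
               "aliased")
})

test_that("a planted exposure interaction is recovered by the full model", {
  cat_f <- factor_catalog(fct_def("grp", c("lo", "hi")))
  co <- simulate_cohort(sim_config(
    cat_f, n = 20000, seed = 6, outcomes = "disease",
    baseline_prev = c(disease = 0.1),
    effects = list(planted_effect("disease", "grp",
                                  interaction = c(hi = 1.0)))))
  fit <- fit_logistic(co, model_spec("disease", main = "grp",
                                     interactions = "grp"))
  i <- grep(":", fit$coef$term)
  expect_lt(abs(fit$coef$estimate[i] - 1.0), 0.15)
})

test_that("greedy stepwise matches the exhaustive AIC optimum", {
  co <- followup_cohort(n = 5000, seed = 1)
  cands <- c("true_f", "decoy1", "decoy2")
  fw <- stepwise_select(co, "disease", cands, direction = "forward")
  bw <- stepwise_select(co, "disease", cands, direction = "backward")
  both <- stepwise_select(co, "disease", cands, direction = "both")
  ex <- exhaustive_aic(co, "disease", cands)
  expect_identical(sort(fw$terms), sort(ex$terms))
  expect_identical(sort(bw$terms), sort(ex$terms))
  expect_identical(sort(both$terms), sort(ex$terms))
  expect_identical(fw$terms, "true_f")
  expect_equal(fw$fit$aic, ex$fit$aic, tolerance = 1e-10)
  # the trace records each move with decreasing AIC
  expect_identical(fw$trace$action, c("start", "add"))
  expect_lt(fw$trace$aic[2], fw$trace$aic[1])
})

test_that("stepwise stops at the base model when there is no signal", {
  co <- followup_cohort(n = 4000, seed = 12, beta = 0)
  fw <- stepwise_select(co, "disease", c("true_f", "decoy1", "decoy2"),
                        direction = "forward")
  expect_length(fw$terms, 0L)
})

test_that("stepwise honours the interaction hierarchy", {
  # strong planted exposure interaction: the interaction term must be worth
  # selecting, but may only enter once its main effect is in
  cat_f <- factor_catalog(fct_def("true_f", c("ref", "hit")),
                          fct_def("decoy1", c("a", "b")))
  co <- simulate_cohort(sim_config(
    cat_f, n = 8000, seed = 15, outcomes = "disease",
    baseline_prev = c(disease = 0.1),
    effects = list(planted_effect("disease", "true_f",
                                  interaction = c(hit = 1.5)))))
  cands <- c("true_f:exposure", "true_f", "decoy1")
  fw <- stepwise_select(co, "disease", cands, direction = "forward")
  expect_true("true_f:exposure" %in% fw$terms)
  tr <- fw$trace[fw$trace$action == "add", ]
  expect_lt(which(tr$term == "true_f"), which(tr$term == "true_f:exposure"))
  # first candidate move cannot be the orphan interaction
  adds <- factorscreen:::eligible_adds(character(), cands, hierarchy = TRUE)
  expect_false("true_f:exposure" %in% adds)
  # backward: the main effect is not droppable while its interaction stays
  drops <- factorscreen:::eligible_drops(c("true_f", "true_f:exposure"),
                                         hierarchy = TRUE)
  expect_identical(drops, "true_f:exposure")
  # with the hierarchy switch off the orphan interaction is a legal move
  adds_free <- factorscreen:::eligible_adds(character(), cands,
                                            hierarchy = FALSE)
  expect_true("true_f:exposure" %in% adds_free)
})
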