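# shared fixtures: all built in code, no files on disk

small_catalog <- function() {
  factor_catalog(
    fct_def("sex", c("male", "female")),
    fct_def("age_group", c("4-6", "7-10", "11-13", "14-17"), ordered = TRUE)
  )
}

# cohort reproducing the printed whole-cohort 2x2 margins of the worked
# example: 78 asthma-only (35 index / 43 reference), 361 rhinitis-only
# (104/257), 72 both (24/48), 4175 no-disease controls (1361/2814)
table1_cohort <- function() {
  blocks <- list(
    c("asthma",   "index",      35), c("asthma",   "reference",   43),
    c("rhinitis", "index",     104), c("rhinitis", "reference",  257),
    c("both",     "index",      24), c("both",     "reference",   48),
    c("none",     "index",    1361), c("none",     "reference", 2814))
  disease <- unlist(lapply(blocks, function(b) rep(b[1L], as.integer(b[3L]))))
  exposure <- unlist(lapply(blocks, function(b) rep(b[2L], as.integer(b[3L]))))
  n <- length(disease)
  df <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    exposure = exposure,
    asthma = ifelse(disease == "asthma", "yes", "no"),
    rhinitis = ifelse(disease == "rhinitis", "yes", "no"),
    both = ifelse(disease == "both", "yes", "no"),
    sex = rep_len(c("male", "female"), n))
  cohort_table(df, factor_catalog(fct_def("sex", c("male", "female"))),
               index_level = "index", reference_level = "reference",
               outcomes = c("asthma", "rhinitis", "both"), strict = TRUE)
}

# random small catalogue for enumeration property tests
random_catalog <- function(seed) {
  set.seed(seed)
  nf <- sample(2:6, 1L)
  fs <- lapply(seq_len(nf), function(i) {
    nl <- sample(2:5, 1L)
    fct_def(sprintf("f%02d", i), sprintf("f%02d_l%d", i, seq_len(nl)))
  })
  factor_catalog(fs)
}

# independent pair-count oracle: explicit double loop, no symmetric-function
# shortcut shared with count_subgroups()
brute_count_depth2 <- function(lc) {
  total <- as.double(sum(lc))
  for (i in seq_along(lc)) {
    for (j in seq_along(lc)) {
      if (i < j) total <- total + lc[i] * lc[j]
    }
  }
  total
}

# tiny simulated cohort for screen/followup tests
toy_sim_cohort <- function(n = 2000, seed = 11, effects = list(),
                           baseline = c(asthma = 0.017, rhinitis = 0.077,
                                        both = 0.015)) {
  cat3 <- factor_catalog(
    fct_def("age_group", c("4-6", "7-10", "11-13", "14-17"), ordered = TRUE),
    fct_def("sex", c("male", "female")),
    fct_def("farm", c("no", "yes")))
  simulate_cohort(sim_config(cat3, n = n, seed = seed, effects = effects,
                             baseline_prev = baseline))
}
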