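Package: factorscreen
Title: Exhaustive Factorial Subgroup Screening for Categorical Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive screening of all one- and two-factorial subgroups of a
    categorical study cohort for heterogeneity in the association between a
    binary exposure and binary disease outcomes. Enumerates every subgroup
    defined by one factor level or a pair of levels from two distinct factors,
    estimates a per-subgroup effect statistic (crude odds ratio with Wald
    confidence limits, or a crude outcome proportion), and supports triage of
    striking factors through funnel and interaction-trend views, random-forest
    permutation importance and minimal depth, and AIC-stepwise logistic
    follow-up models. Includes a seeded synthetic-cohort simulator with
    plantable exposure-by-factor interaction effects so the whole screening
    workflow can be exercised and validated without access to restricted
    survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ranger,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
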