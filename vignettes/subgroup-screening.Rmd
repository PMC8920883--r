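---
title: "Exhaustive factorial subgroup screening: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive factorial subgroup screening: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(factorscreen)
```

## The problem

In observational cohorts the association between a binary exposure (here the
archetype is socioeconomic status, dichotomised to low vs high) and a binary
disease outcome (current asthma, allergic rhinitis, or both) is rarely
homogeneous. Conventional practice inspects a handful of pre-chosen
subgroups; `factorscreen` instead repeats the primary analysis in *every*
subgroup that can be formed from a catalogue of categorical factors — every
single factor level, and every pair of levels from two distinct factors —
and presents the resulting estimates for human triage. For a catalogue of
factors with level counts $l_1, \dots, l_p$ the number of subgroups at depth
cap 2 is

$$ N_{\le 2} \;=\; \sum_i l_i \;+\; \sum_{i<j} l_i\, l_j
   \;=\; \sum_i l_i + \frac{(\sum_i l_i)^2 - \sum_i l_i^2}{2}, $$

implemented for arbitrary depth caps through elementary symmetric
polynomials and cross-checked against brute-force enumeration in the test
suite. Depth 2 is the default: deeper conjunctions multiply overlap, shrink
cells, and resist interpretation; depth 3 and beyond remain available but
off by default.

The screening philosophy is deliberately estimation-only. No per-subgroup
p-values or multiplicity adjustments are computed: with tens of thousands of
overlapping subgroups, a significance lens invites exactly the binary
classifications the approach wants to avoid. "Striking" is a human judgment,
supported by the funnel view, trend plots, and rank orderings
(`striking_ranks()` sorts by log-scale deviation from the overall estimate,
optionally weighted by $\sqrt{n}$) — never an automatic label.

## Per-subgroup statistics

Within a subgroup, subjects are cross-tabulated as exposure (index vs
reference arm) against case/control status. Each outcome is screened in its
own universe: cases of that outcome against the *common control group* of
subjects negative on every declared outcome, so the per-outcome screens stay
disjoint and do not contaminate one another through subjects carrying the
other disease. The crude odds ratio is the cross product $(ad)/(bc)$ with
its Wald interval $\exp(\ln \mathrm{OR} \pm z\sqrt{1/a+1/b+1/c+1/d})$. The
same estimate is available through an iteratively reweighted logistic fit
(`logistic_or()`), and the two agree to $10^{-6}$ relative error on
non-degenerate tables — the saturated-model identity that the test suite
enforces on random tables.

Degenerate tables are encoded, never raised: a zero numerator gives 0, a
zero denominator $\infty$, both give `NaN`, and the Wald interval is
undefined (flagged) whenever any cell is zero. No continuity correction is
applied by default — extreme odds ratios are real outputs of sparse cells
and are kept — but a Haldane–Anscombe $+0.5$ option exists. For display the
point estimate is clamped into $[0.3, 15]$ (both configurable): infinite
values render at the upper bound, zero and undefined values at the lower
bound, and the untruncated value is always stored alongside. Orientation is
explicit configuration: the index arm's odds form the numerator, so OR > 1
always means higher odds under index exposure, regardless of label sort
order.

The alternative statistic is the crude outcome proportion, ignoring the
exposure split. Its denominator follows the same control-rule switch:
against the common control group (the screen's default, which is what makes
per-subgroup proportions comparable across the disjoint outcome screens) or
against all subjects (the convention behind whole-cohort prevalence
figures). Both conventions appear in published summaries of the same data,
which is why the switch exists rather than a single hard-coded rule.

## Data preparation

Exclusion rules (`apply_exclusions()`) drop exposure arms outside the binary
contrast, rows missing any listed column, and rows failing an optional
predicate (e.g. an age band where the diagnosis is unreliable). Rules are
applied jointly, but the tally attributes each dropped row to the first rule
it fails, in declared order, making the tally deterministic and summable.

Missing *factor* values are then recoded to an explicit `"no data"` level
(`recode_missing_to_nodata()`), so systematic missingness surfaces as its
own subgroup instead of silently shrinking others. The `"no data"` level is
excluded from trend sequences (it has no position on an ordinal scale) and
the random-forest triage by default runs on the pre-recoding representation
with missing rows omitted. Numeric sources are binned right-closed
(`cut_points[i-1] < v \le cut_points[i]`, open extremes) — stated explicitly
because integer age bands make the convention invisible.

CSV dialect is fixed for reproducibility: UTF-8, comma-separated, header
required, empty fields and `NA` read as missing (extra tokens
configurable). A write/read round trip reproduces a cohort exactly.

## Funnel, trend, and comparison views

Plotting every subgroup's estimate against its size yields a funnel:
small subgroups scatter widely around the overall estimate, large ones hug
it. Subgroups that escape the funnel at *large* size are the interesting
ones. `interaction_trend()` reads the depth-1 estimates of an ordered
factor in declared level order and classifies the sequence as increasing or
decreasing only when every consecutive pair moves strictly in the same
direction — ties and any non-finite estimate yield `"none"`. Strictness is
intentional: a flat pair is no evidence of a trend, and an undefined
estimate should never be interpolated over. `compare_outcomes()` pairs two
outcomes per subgroup for bubble-style comparison against both overall
references.

`min_report_n` is a reporting filter only. Every subgroup is computed, so
extreme small-n anomalies remain discoverable; rows below the threshold are
flagged, not dropped.

## Random-forest triage

The forest answers a different question from the screen: which factors carry
predictive information about the outcome at all, exposure aside. Before
fitting, `correlation_filter()` computes pairwise bias-corrected Cramér's V
(Bergsma's correction of the $\chi^2$-based $\phi^2$) and, from each pair
above 0.9 (configurable), drops the factor with more levels — the
higher-cardinality member is the more redundant and the more split-favoured
one (ties go to the later catalogue position).

Trees are grown on bootstrap samples with extremely-randomized split-point
selection: `nsplit` random cut candidates per factor, `mtry` candidate
factors per split, terminal nodes of at least `nodesize`. These three
hyperparameters are grid-searched on out-of-bag (OOB) misclassification
error, with ties resolved toward smaller `nodesize` then smaller `mtry`
(the less complex configuration). Training uses an 80/20 split; the 20%
hold-out yields an additional test error. Defaults: 500 trees, grids
centred on `nodesize` 10, `nsplit` 2, `mtry` 3. The fitting engine is
`ranger`; categorical predictors are handled by level-index order rather
than exhaustive partition search, which is the only tractable choice for
high-cardinality factors.

Permutation importance (VIMP) is the increase in OOB error after permuting
a factor's out-of-bag values: positive marks signal, near-zero or negative
marks noise, and a factor never used by any tree scores exactly 0. Minimal
depth is computed in-package from the stored tree structures: per tree, the
depth of the shallowest split on the factor (root = 0), with factors absent
from a tree assigned that tree's maximal depth + 1 — deeper than anything
actually used; the convention matters and is therefore documented here. The
selection threshold (the dashed line of the importance plot) is the mean of
the per-factor mean minimal depths: under uninformative ordering no factor
is expected to beat the average, so factors below it are flagged.

All randomness — the 80/20 split, each grid fit, the permutations — derives
from one master seed through a documented substream map, so runs are exactly
reproducible.

## Follow-up models

Striking factors feed a multivariable logistic model of the outcome on the
exposure, factor main effects, and factor-by-exposure interactions, with
treatment coding against explicit reference levels. Fits use IRLS (relative
deviance change $\le 10^{-8}$, max 100 iterations); rank deficiency is an
error naming the aliased terms, and separation is flagged from the
coefficient/SE profile. Every fit reports AIC
($-2\ell + 2k$, asserted as an identity in the tests) and a likelihood-ratio
test against the intercept-only model on the same rows.

Stepwise selection is greedy over single-term moves in forward, backward,
or bidirectional mode, stopping when no move lowers AIC, with ties broken
by candidate declaration order. The interaction hierarchy is enforced by
default (an interaction may enter only while its main effect is present; a
main effect may leave only after its interactions) and can be disabled. All
candidate fits share one model frame built by listwise deletion over the
union of candidate variables — otherwise AICs are not comparable across the
lattice. Known limitation: greedy backward elimination can stall in a local
AIC optimum when a jointly-null main-effect/interaction pair is in the
model, because no *single* drop improves the criterion even though the pair
jointly would; the exhaustive-AIC search (`exhaustive_aic()`) is the
reference on small lattices and the package runs all three directions so
such disagreements are visible rather than assumed away.

## The synthetic cohort generator

Because the motivating survey data are access-restricted, the generator is
first-class, tested code, and every recovery claim in this package is made
against it. It emulates the *structure* of a large cross-sectional allergy
survey, not the marginal distributions of any named variable:

* factors drawn independently from declared level marginals (uniform by
  default);
* a binary exposure with index-arm probability 0.325 — the low-SES share of
  the motivating cohort;
* mutually exclusive outcomes drawn as **one multinomial** over
  {asthma-only, rhinitis-only, both, none} with baseline prevalences
  1.7%, 7.7% and 1.5%. One multinomial, rather than three correlated
  Bernoullis, mirrors disjoint outcome groups plus a common no-disease
  control group exactly;
* planted effects adding log-odds by factor level (main) and, in the index
  arm only, interaction log-odds — the signal the screen must detect. An
  ordered factor can take a linear log-odds trend instead of per-level
  values;
* missingness applied after outcome generation, never touching exposure or
  outcomes.

Because outcomes are multinomial against a "none" baseline and the screen
uses no-disease controls, the screened odds ratio implied for a planted
level is *exactly* `exp(interaction)`; the generator emits this ground
truth alongside the cohort, so recovery tests need no second simulator.

`survey_default_config()` is the structural stand-in for the motivating
survey: 56 factors comprising 221 levels — one of 58 levels, one of 7, one
of 5, forty-five ordered 3-level factors and eight binary ones. This is the
unique level-count profile consistent with the published totals of 221
single levels and 22,704 depth-2 subgroups ($\sum l = 221$,
$\sum l^2 = 3875$); the 58-level factor exists to complete that identity
and is structural, not substantive. What passing recovery tests on these
cohorts does *not* show: robustness to correlated factors, informative
missingness, or survey-design effects (weights are intentionally out of
scope) — real data have all three.

## Numerical choices and test scales

* Wald intervals use $z = 1.959964$ at 95%; closed-form and logistic CIs
  agree because both are Wald-on-log-odds constructions.
* Screening is vectorised by integer tabulation per factor and factor pair,
  so a 22,704-subgroup screen of a 50,000-subject cohort runs in seconds;
  depth caps above 2 fall back to membership masks.
* Simulation sizes in the tests follow the operating points of the claims
  they check: n = 50,000 for recovering a planted interaction OR of 3
  within ±25%; 100 seeded forests at n = 3,000 for rank-first recovery of a
  planted predictor; ten replicate null cohorts of n = 50,000 for the
  false-striking rate of large depth-1 subgroups (the 2–8% band around the
  nominal 5% is measured as a mean over replicates, because subgroups of
  one cohort share its overall draw and a single replicate's fraction is
  correlated noise); 100 replicates at n = 20,000 for monotone trend
  detection.
* Report rounding follows the field's presentation conventions — two
  decimals for odds ratios and confidence limits, one for percentages —
  and only in human-readable output; serialised results keep full
  precision.

## A worked miniature

```{r example}
cat3 <- factor_catalog(
  fct_def("age_group", c("4-6", "7-10", "11-13", "14-17"), ordered = TRUE),
  fct_def("sex", c("male", "female")),
  fct_def("farm", c("no", "yes")))

cfg <- sim_config(cat3, n = 20000, seed = 7, effects = list(
  planted_effect("asthma", "age_group",
                 interaction_trend = c(log(3), log(1/3)))))
cohort <- simulate_cohort(cfg)

res <- run_screen(cohort, screen_config())
res
interaction_trend(res, "age_group", "asthma")
head(striking_ranks(res, "asthma"), 4)
```

The planted decreasing interaction shows up as a strictly decreasing
odds-ratio sequence over the age groups, and the affected levels lead the
deviation ranking — which is exactly the route from screen to follow-up
model a user would take on real data.
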