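#' Truncation bounds for display values
#'
#' Extreme per-subgroup odds ratios (driven by small or empty cells) are
#' computed in full but clamped for visualisation, so one wild subgroup does
#' not flatten the funnel. Defaults clamp at 0.3 and 15.
#'
#' @param low,high Positive truncation bounds, `low < high`.
#' @return A `trunc_config`.
#' @export
trunc_config <- function(low = 0.3, high = 15) {
  stopifnot(low > 0, high > 0, low < high)
  structure(list(low = low, high = high), class = "trunc_config")
}

#' A 2x2 exposure-by-outcome table
#'
#' Cell layout: `a` cases in the index-exposure arm, `b` cases in the
#' reference arm, `c` non-cases (controls) in the index arm, `d` controls in
#' the reference arm.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  structure(as.list(cells), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("case", "control"), c("index", "reference")))
  print(m)
  invisible(x)
}

#' Cross-tabulate exposure by outcome within a subgroup
#'
#' Cases are subjects with `outcome == "yes"`. The control set is chosen by
#' `control`: `"neither"` (default) uses subjects negative on *every* declared
#' outcome — the common control group, keeping the per-outcome screens
#' disjoint — while `"all"` uses every non-case. Subjects that are neither
#' cases nor controls (they have one of the other diseases) are excluded from
#' the table, as are subjects with missing exposure.
#'
#' @param cohort A `cohort_table`.
#' @param outcome Outcome column name.
#' @param sg Optional `subgroup`; `NULL` tabulates the whole cohort.
#' @param control `"neither"` or `"all"`.
#' @return A `two_by_two` with attribute `empty` flagging an all-zero table.
#' @export
crosstab <- function(cohort, outcome, sg = NULL, control = c("neither", "all")) {
  control <- match.arg(control)
  m <- cohort_meta(cohort)
  if (!outcome %in% m$outcomes) stop("unknown outcome: ", outcome)
  df <- as.data.frame(cohort)
  if (!is.null(sg)) df <- df[df[[m$id]] %in% members(sg, cohort), , drop = FALSE]
  st <- case_control_status(df, outcome, m$outcomes, control)
  ex <- df[[m$exposure]]
  use <- !is.na(st) & !is.na(ex) & ex %in% c(m$index_level, m$reference_level)
  st <- st[use]; idx <- ex[use] == m$index_level
  tab <- two_by_two(a = sum(st & idx), b = sum(st & !idx),
                    c = sum(!st & idx), d = sum(!st & !idx))
  attr(tab, "empty") <- with(tab, a + b + c + d) == 0L
  tab
}

# TRUE = case, FALSE = control, NA = excluded (other disease)
case_control_status <- function(df, outcome, outcomes, control) {
  case <- !is.na(df[[outcome]]) & df[[outcome]] == "yes"
  if (control == "all") {
    ctrl <- !is.na(df[[outcome]]) & df[[outcome]] == "no"
  } else {
    ctrl <- rep(TRUE, nrow(df))
    for (oc in outcomes) {
      ctrl <- ctrl & !is.na(df[[oc]]) & df[[oc]] == "no"
    }
  }
  out <- rep(NA, nrow(df))
  out[ctrl] <- FALSE
  out[case] <- TRUE
  out
}

# vectorised cross-product OR with the degenerate-cell encoding:
# numerator a*d, denominator b*c; 0/x -> 0, x/0 -> Inf, 0/0 -> NaN
or_point <- function(a, b, c, d) {
  num <- a * d
  den <- b * c
  out <- num / den
  out[num == 0 & den > 0] <- 0
  out[num > 0 & den == 0] <- Inf
  out[num == 0 & den == 0] <- NaN
  out
}

or_ci_bounds <- function(a, b, c, d, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  lo <- exp(log(or_point(a, b, c, d)) - z * se)
  hi <- exp(log(or_point(a, b, c, d)) + z * se)
  lo[!ok] <- NA_real_; hi[!ok] <- NA_real_
  list(low = lo, high = hi)
}

#' Crude odds ratio of a 2x2 table
#'
#' The cross-product estimate `(a d) / (b c)`, with no continuity correction:
#' a zero numerator gives 0, a zero denominator with positive numerator gives
#' `Inf`, and a zero in both gives the undefined value `NaN` — degenerate
#' tables are encoded, never raised as errors, so small subgroups stay
#' discoverable. Optionally adds a Haldane–Anscombe +0.5 correction.
#'
#' @param tab A `two_by_two`.
#' @param correction If `TRUE`, add 0.5 to each cell before the cross product
#'   (off by default).
#' @return An `effect_estimate` with the point value; CI fields are `NA`
#'   until [wald_ci()] is applied.
#' @export
odds_ratio <- function(tab, correction = FALSE) {
  stopifnot(inherits(tab, "two_by_two"))
  cells <- unlist(tab[c("a", "b", "c", "d")])
  if (correction) cells <- cells + 0.5
  point <- unname(or_point(cells[1L], cells[2L], cells[3L], cells[4L]))
  effect_estimate("odds_ratio", point = point, n = sum(unlist(tab)),
                  flags = c(if (isTRUE(attr(tab, "empty"))) "empty",
                            if (!is.finite(point)) "degenerate"))
}

#' Wald confidence interval for a 2x2 odds ratio
#'
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z` the
#' standard-normal quantile of the coverage (1.959964 at 0.95). Requires all
#' four cells positive; otherwise the interval is undefined (`NA`) and
#' flagged, while the point estimate keeps its [odds_ratio()] encoding.
#'
#' @param tab A `two_by_two`.
#' @param level Coverage, default 0.95.
#' @return Named numeric `c(low, high)`; `NA`s carry attribute
#'   `undefined = TRUE`.
#' @export
wald_ci <- function(tab, level = 0.95) {
  stopifnot(inherits(tab, "two_by_two"))
  b <- or_ci_bounds(tab$a, tab$b, tab$c, tab$d, level)
  out <- c(low = b$low, high = b$high)
  if (anyNA(out)) attr(out, "undefined") <- TRUE
  out
}

effect_estimate <- function(kind, point, ci_low = NA_real_, ci_high = NA_real_,
                            n = NA_integer_, flags = character()) {
  structure(list(kind = kind, point = point,
                 ci_low = ci_low, ci_high = ci_high,
                 n = n, display = NA_real_, flags = as.character(flags)),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat("<effect_estimate> ", x$kind, ": ",
      formatC(x$point, digits = 4, format = "g"), sep = "")
  if (!is.na(x$ci_low)) {
    cat(" (", formatC(x$ci_low, digits = 4, format = "g"), "-",
        formatC(x$ci_high, digits = 4, format = "g"), ")", sep = "")
  }
  cat("  n=", x$n, sep = "")
  if (length(x$flags)) cat("  [", paste(x$flags, collapse = ","), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Odds ratio by iterative logistic fit
#'
#' Fits `outcome ~ exposure` by maximum likelihood (IRLS via [stats::glm()])
#' on the case/control subset and exponentiates the slope. On non-degenerate
#' tables this equals the closed-form cross-product OR (the saturated
#' binary-model identity); a zero cell means separation, which is detected
#' and encoded with the closed-form degenerate rules plus a `separation`
#' flag. A subset with only one exposure arm is undefined.
#'
#' @inheritParams crosstab
#' @param level CI coverage for the Wald interval on the coefficient scale.
#' @return An `effect_estimate` (kind `"odds_ratio"`).
#' @export
logistic_or <- function(cohort, outcome, sg = NULL,
                        control = c("neither", "all"), level = 0.95) {
  control <- match.arg(control)
  m <- cohort_meta(cohort)
  tab <- crosstab(cohort, outcome, sg = sg, control = control)
  arms_present <- (tab$a + tab$c > 0) + (tab$b + tab$d > 0)
  if (arms_present < 2L) {
    return(effect_estimate("odds_ratio", NaN, n = sum(unlist(tab[1:4])),
                           flags = c("single_arm", "undefined")))
  }
  if (with(tab, a == 0 || b == 0 || c == 0 || d == 0)) {
    est <- odds_ratio(tab)
    est$flags <- unique(c(est$flags, "separation"))
    return(est)
  }
  # expand the 2x2: glm on grouped binomial data is exact and fast
  dat <- data.frame(
    y = c(1, 1, 0, 0),
    x = c(1, 0, 1, 0),
    w = c(tab$a, tab$b, tab$c, tab$d)
  )
  fit <- stats::glm(y ~ x, family = stats::binomial(), data = dat, weights = w,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  co <- stats::coef(fit)[["x"]]
  se <- sqrt(stats::vcov(fit)["x", "x"])
  z <- stats::qnorm(1 - (1 - level) / 2)
  flags <- if (!fit$converged) "nonconvergence" else character()
  if (length(flags)) {
    est <- odds_ratio(tab)
    est$flags <- unique(c(est$flags, flags))
    return(est)
  }
  effect_estimate("odds_ratio", point = exp(co),
                  ci_low = exp(co - z * se), ci_high = exp(co + z * se),
                  n = sum(unlist(tab[1:4])))
}

#' Crude outcome proportion in a subgroup
#'
#' Cases over cases-plus-controls, ignoring the exposure split. With
#' `control = "neither"` the denominator is the case/control universe of the
#' screen (cases of this outcome plus no-disease controls); with
#' `control = "all"` it is every subject with a non-missing outcome, the
#' convention behind whole-cohort prevalences.
#'
#' @inheritParams crosstab
#' @param level CI coverage for the Wald binomial interval.
#' @return An `effect_estimate` (kind `"proportion"`, scale 0..1).
#' @export
crude_proportion <- function(cohort, outcome, sg = NULL,
                             control = c("neither", "all"), level = 0.95) {
  control <- match.arg(control)
  m <- cohort_meta(cohort)
  df <- as.data.frame(cohort)
  if (!is.null(sg)) df <- df[df[[m$id]] %in% members(sg, cohort), , drop = FALSE]
  st <- case_control_status(df, outcome, m$outcomes, control)
  n <- sum(!is.na(st))
  if (n == 0L) {
    return(effect_estimate("proportion", NaN, n = 0L,
                           flags = c("empty", "undefined")))
  }
  cases <- sum(st, na.rm = TRUE)
  p <- cases / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(p * (1 - p) / n)
  effect_estimate("proportion", point = p,
                  ci_low = max(0, p - z * se), ci_high = min(1, p + z * se),
                  n = n)
}

#' Clamp an estimate into the display range
#'
#' The stored point and CI are never altered; only `display` is set:
#' finite points are clamped into `[low, high]`, infinite points display at
#' `high`, zero and undefined points at `low`, all with a `truncated` flag.
#' Idempotent.
#'
#' @param est An `effect_estimate` (or bare numeric vector).
#' @param cfg A [trunc_config()].
#' @return The estimate with `display` filled (or the clamped numeric).
#' @export
truncate_display <- function(est, cfg = trunc_config()) {
  stopifnot(inherits(cfg, "trunc_config"))
  if (is.numeric(est)) {
    out <- pmin(pmax(est, cfg$low), cfg$high)
    out[!is.na(est) & is.infinite(est) & est > 0] <- cfg$high
    out[is.nan(est) | (!is.na(est) & est == 0)] <- cfg$low
    return(out)
  }
  stopifnot(inherits(est, "effect_estimate"))
  p <- est$point
  disp <- if (is.nan(p) || p == 0) cfg$low
          else if (is.infinite(p)) cfg$high
          else min(max(p, cfg$low), cfg$high)
  if (!identical(disp, p)) est$flags <- unique(c(est$flags, "truncated"))
  est$display <- disp
  est
}
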