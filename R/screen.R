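#' Configuration of a subgroup screen
#'
#' @param outcomes Outcome columns to screen; default all outcomes declared
#'   on the cohort.
#' @param depth Subgroup depth cap (default 2: single levels and
#'   cross-factor level pairs).
#' @param statistic `"odds_ratio"` (exposure association per subgroup) or
#'   `"proportion"` (crude outcome proportion per subgroup, exposure
#'   ignored).
#' @param control Control-group rule passed to [crosstab()]:
#'   `"neither"` (common no-disease control group, default) or `"all"`.
#' @param truncation A [trunc_config()] for display values, or `NULL` for
#'   the statistic's default (0.3–15 for odds ratios; no truncation for
#'   proportions).
#' @param min_report_n Subgroups smaller than this are flagged
#'   `below_min_n` in results. A reporting filter only: every subgroup is
#'   still computed, so extreme small-n abnormalities stay discoverable.
#' @param level Coverage of the per-row Wald intervals.
#' @param seed Integer seed recorded for downstream randomized steps; the
#'   screen itself is deterministic.
#' @return A `screen_config`.
#' @export
screen_config <- function(outcomes = NULL, depth = 2L,
                          statistic = c("odds_ratio", "proportion"),
                          control = c("neither", "all"),
                          truncation = NULL, min_report_n = 0L,
                          level = 0.95, seed = 1L) {
  statistic <- match.arg(statistic)
  control <- match.arg(control)
  if (!is.null(truncation)) stopifnot(inherits(truncation, "trunc_config"))
  else if (statistic == "odds_ratio") truncation <- trunc_config()
  stopifnot(depth >= 1L, min_report_n >= 0L)
  structure(list(outcomes = outcomes, depth = as.integer(depth),
                 statistic = statistic, control = control,
                 truncation = truncation,
                 min_report_n = as.integer(min_report_n),
                 level = level, seed = as.integer(seed)),
            class = "screen_config")
}

#' Run the exhaustive subgroup screen
#'
#' Computes the configured statistic for every enumerated subgroup crossed
#' with every outcome: one result row per (subgroup, outcome), in canonical
#' subgroup order, plus a whole-cohort overall row per outcome (the funnel
#' reference). Empty and single-exposure-arm subgroups are flagged rather
#' than dropped, so the result table always has
#' `n_subgroups x n_outcomes` rows.
#'
#' The computation is vectorised by factor (and factor pair): counts come
#' from integer tabulation, so runtime scales linearly in subjects and in
#' subgroups x outcomes.
#'
#' @param cohort A `cohort_table`.
#' @param cfg A [screen_config()].
#' @return A `screen_result`: list with `rows` (data.frame), `overall`
#'   (one row per outcome), `subgroups` (the enumerated `subgroup_set`),
#'   and `config`.
#' @export
run_screen <- function(cohort, cfg = screen_config()) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(cfg, "screen_config"))
  m <- cohort_meta(cohort)
  outcomes <- cfg$outcomes %||% m$outcomes
  if (!length(outcomes)) stop("no outcomes to screen")
  bad <- setdiff(outcomes, m$outcomes)
  if (length(bad)) stop("unknown outcomes: ", paste(bad, collapse = ", "))

  sgs <- enumerate_subgroups(m$catalog, depth = cfg$depth)
  df <- as.data.frame(cohort)
  ex <- df[[m$exposure]]
  is_index <- !is.na(ex) & ex == m$index_level
  is_ref <- !is.na(ex) & ex == m$reference_level

  fnames <- sort(names(m$catalog))
  codes <- lapply(fnames, function(f) match(df[[f]], m$catalog[[f]]$levels))
  names(codes) <- fnames
  nlev <- vapply(fnames, function(f) length(m$catalog[[f]]$levels), integer(1L))

  per_outcome <- lapply(outcomes, function(oc) {
    st <- case_control_status(df, oc, m$outcomes, cfg$control)
    case <- !is.na(st) & st
    ctrl <- !is.na(st) & !st
    cnt <- if (cfg$depth <= 2L) {
      screen_counts(codes, nlev, cfg$depth,
                    a = case & is_index, b = case & is_ref,
                    c = ctrl & is_index, d = ctrl & is_ref)
    } else {
      screen_counts_generic(sgs, df, m,
                            a = case & is_index, b = case & is_ref,
                            c = ctrl & is_index, d = ctrl & is_ref)
    }
    out <- cbind(sgs[c("key", "depth", intersect(names(sgs),
              c(paste0("factor", 1:9), paste0("level", 1:9))))],
              outcome = oc, cnt, row.names = NULL)
    # overall (depth-0) reference row
    ov <- data.frame(outcome = oc,
                     n_total = nrow(df),
                     a = sum(case & is_index), b = sum(case & is_ref),
                     c = sum(ctrl & is_index), d = sum(ctrl & is_ref))
    list(rows = out, overall = ov)
  })
  rows <- do.call(rbind, lapply(per_outcome, `[[`, "rows"))
  overall <- do.call(rbind, lapply(per_outcome, `[[`, "overall"))
  rows <- add_estimates(rows, cfg)
  overall$n <- with(overall, a + b + c + d)
  overall <- add_estimates(overall, cfg)
  structure(list(rows = rows, overall = overall, subgroups = sgs,
                 config = cfg, exposure = m$exposure,
                 index_level = m$index_level),
            class = "screen_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# tabulate the four 2x2 cells for every depth-1 level and depth-2 level pair
screen_counts <- function(codes, nlev, depth, a, b, c, d) {
  fnames <- names(codes)
  tab4 <- function(code, nbins) {
    cbind(a = tabulate(code[a], nbins), b = tabulate(code[b], nbins),
          c = tabulate(code[c], nbins), d = tabulate(code[d], nbins),
          n_total = tabulate(code, nbins))
  }
  blocks <- lapply(fnames, function(f) tab4(codes[[f]], nlev[[f]]))
  if (depth >= 2L && length(fnames) >= 2L) {
    for (pair in utils::combn(seq_along(fnames), 2L, simplify = FALSE)) {
      i <- pair[1L]; j <- pair[2L]
      code <- (codes[[i]] - 1L) * nlev[[j]] + codes[[j]]
      blocks[[length(blocks) + 1L]] <- tab4(code, nlev[[i]] * nlev[[j]])
    }
  }
  out <- as.data.frame(do.call(rbind, blocks))
  out$n <- out$a + out$b + out$c + out$d
  out
}

# membership-mask fallback for depth caps beyond the vectorised pair path
screen_counts_generic <- function(sgs, df, m, a, b, c, d) {
  maxd <- max(sgs$depth)
  out <- matrix(0L, nrow(sgs), 5L,
                dimnames = list(NULL, c("a", "b", "c", "d", "n_total")))
  for (i in seq_len(nrow(sgs))) {
    keep <- rep(TRUE, nrow(df))
    for (k in seq_len(maxd)) {
      f <- sgs[[paste0("factor", k)]][i]
      if (is.na(f)) break
      v <- df[[f]]
      keep <- keep & !is.na(v) & v == sgs[[paste0("level", k)]][i]
    }
    out[i, ] <- c(sum(a & keep), sum(b & keep), sum(c & keep),
                  sum(d & keep), sum(keep))
  }
  out <- as.data.frame(out)
  out$n <- out$a + out$b + out$c + out$d
  out
}

add_estimates <- function(rows, cfg) {
  if (cfg$statistic == "odds_ratio") {
    rows$point <- or_point(rows$a, rows$b, rows$c, rows$d)
    ci <- or_ci_bounds(rows$a, rows$b, rows$c, rows$d, cfg$level)
    rows$ci_low <- ci$low; rows$ci_high <- ci$high
  } else {
    cases <- rows$a + rows$b
    p <- cases / rows$n
    z <- stats::qnorm(1 - (1 - cfg$level) / 2)
    se <- sqrt(p * (1 - p) / rows$n)
    rows$point <- p
    rows$ci_low <- pmax(0, p - z * se)
    rows$ci_high <- pmin(1, p + z * se)
  }
  rows$display <- if (is.null(cfg$truncation)) rows$point else
    truncate_display(rows$point, cfg$truncation)
  rows$empty <- rows$n_total == 0L
  rows$single_arm <- (rows$a + rows$c == 0L) | (rows$b + rows$d == 0L)
  rows$zero_cell <- rows$a == 0L | rows$b == 0L | rows$c == 0L | rows$d == 0L
  rows$below_min_n <- rows$n < cfg$min_report_n
  rows
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Subgroup screen: ", nrow(x$subgroups), " subgroups x ",
      nrow(x$overall), " outcome(s) = ", nrow(x$rows), " rows (",
      x$config$statistic, ")\n", sep = "")
  for (i in seq_len(nrow(x$overall))) {
    cat("  overall ", x$overall$outcome[i], ": ",
        formatC(x$overall$point[i], digits = 3, format = "g"),
        " (n = ", x$overall$n[i], ")\n", sep = "")
  }
  invisible(x)
}

#' Funnel-plot table for one outcome
#'
#' One row per subgroup: size on the x axis, truncated statistic on the y
#' axis, with the whole-cohort estimate as the horizontal reference line.
#' Small subgroups scatter widely around the reference and large ones hug
#' it; deviations from that funnel mark candidate striking subgroups.
#'
#' @param result A `screen_result`.
#' @param outcome One screened outcome.
#' @param drop_empty Drop rows with no members (default `TRUE`; they have no
#'   position in the funnel).
#' @return A data.frame `(key, depth, n, display, point, below_min_n)` with
#'   attribute `reference` (overall display value).
#' @export
funnel_data <- function(result, outcome, drop_empty = TRUE) {
  stopifnot(inherits(result, "screen_result"))
  r <- result$rows[result$rows$outcome == outcome, , drop = FALSE]
  if (!nrow(r) && !outcome %in% result$overall$outcome) {
    stop("outcome not in screen result: ", outcome)
  }
  if (drop_empty) r <- r[!r$empty, , drop = FALSE]
  out <- r[c("key", "depth", "n", "display", "point", "below_min_n")]
  rownames(out) <- NULL
  attr(out, "reference") <-
    result$overall$display[result$overall$outcome == outcome]
  out
}

#' Pair per-subgroup estimates of two outcomes
#'
#' The "compare" view: one record per subgroup holding the estimate for each
#' outcome, plus both overall references, for bubble-style plots of, e.g.,
#' asthma vs rhinitis proportions. Subgroups lacking a finite estimate on
#' either axis are flagged.
#'
#' @param result A `screen_result`.
#' @param outcome_x,outcome_y Two screened outcomes.
#' @return A data.frame with attribute `reference` `(x, y)`.
#' @export
compare_outcomes <- function(result, outcome_x, outcome_y) {
  stopifnot(inherits(result, "screen_result"))
  rx <- result$rows[result$rows$outcome == outcome_x, , drop = FALSE]
  ry <- result$rows[result$rows$outcome == outcome_y, , drop = FALSE]
  if (!nrow(rx) || !nrow(ry)) stop("both outcomes must be present in the result")
  stopifnot(identical(rx$key, ry$key))
  out <- data.frame(key = rx$key, depth = rx$depth,
                    n_x = rx$n, n_y = ry$n,
                    display_x = rx$display, display_y = ry$display,
                    point_x = rx$point, point_y = ry$point)
  out$missing_either <- !is.finite(out$point_x) | !is.finite(out$point_y)
  attr(out, "reference") <- c(
    x = result$overall$display[result$overall$outcome == outcome_x],
    y = result$overall$display[result$overall$outcome == outcome_y])
  out
}

#' Interaction trend of an ordered factor
#'
#' Reads the depth-1 estimates of one ordered factor in declared level order
#' (the interaction line plot) and classifies the trend: `"decreasing"` iff
#' every consecutive pair of estimates strictly decreases, `"increasing"`
#' symmetrically, otherwise `"none"`. Ties break monotonicity, and any
#' non-finite estimate in the sequence yields `"none"`. The `"no data"`
#' level is excluded from the sequence: it carries no position on the scale.
#'
#' @param result A `screen_result`.
#' @param factor Name of an ordered catalogue factor.
#' @param outcome One screened outcome.
#' @return A `trend_report`: list `(factor, outcome, levels, estimates,
#'   direction)`.
#' @export
interaction_trend <- function(result, factor, outcome) {
  stopifnot(inherits(result, "screen_result"))
  cat <- attr(result$subgroups, "catalog")
  fd <- cat[[factor]]
  if (is.null(fd)) stop("unknown factor: ", factor)
  if (!fd$ordered) stop("factor '", factor, "' is not ordered; no trend defined")
  levs <- setdiff(fd$levels, NODATA)
  r <- result$rows
  r <- r[r$outcome == outcome & r$depth == 1L & r$factor1 == factor, ,
         drop = FALSE]
  est <- r$point[match(levs, r$level1)]
  direction <- trend_direction(est)
  structure(list(factor = factor, outcome = outcome, levels = levs,
                 estimates = est, direction = direction),
            class = "trend_report")
}

trend_direction <- function(est) {
  if (length(est) < 2L || any(!is.finite(est))) return("none")
  d <- diff(est)
  if (all(d < 0)) "decreasing" else if (all(d > 0)) "increasing" else "none"
}

#' @export
print.trend_report <- function(x, ...) {
  cat("Trend for ", x$factor, " / ", x$outcome, ": ", x$direction, "\n",
      sep = "")
  print(stats::setNames(round(x$estimates, 3), x$levels))
  invisible(x)
}

#' Rank subgroups by how striking they look
#'
#' No significance labels are assigned — "striking" is a human judgment —
#' but two orderings help triage: distance of the (truncated) estimate from
#' the overall reference on the log scale (for odds ratios) or absolute
#' scale (for proportions), and the same distance weighted by `sqrt(n)` to
#' penalise pure small-n noise.
#'
#' @param result A `screen_result`.
#' @param outcome One screened outcome.
#' @return The funnel table ordered by decreasing deviation, with columns
#'   `deviation` and `weighted_deviation`.
#' @export
striking_ranks <- function(result, outcome) {
  fd <- funnel_data(result, outcome)
  ref <- attr(fd, "reference")
  dev <- if (result$config$statistic == "odds_ratio") {
    abs(log(fd$display) - log(ref))
  } else {
    abs(fd$display - ref)
  }
  fd$deviation <- dev
  fd$weighted_deviation <- dev * sqrt(fd$n)
  fd[order(-fd$deviation), , drop = FALSE]
}
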