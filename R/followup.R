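#' Specify a multivariable logistic follow-up model
#'
#' Striking factors from the screen are carried into a confirmatory-style
#' multivariable logistic regression of one outcome on the exposure, main
#' factor effects, and factor-by-exposure interaction terms. Factors use
#' treatment (reference-level) dummy coding; reference levels are explicit
#' configuration, defaulting to each factor's first declared level.
#'
#' @param outcome Outcome column name.
#' @param main Character vector of factor names entering as main effects.
#' @param interactions Factor names whose exposure interaction enters; each
#'   must also appear in `main`.
#' @param refs Named list/character of reference levels per factor.
#' @param include_exposure Keep the exposure main effect in the model
#'   (default `TRUE`; required whenever interactions are present).
#' @return A `model_spec`.
#' @export
model_spec <- function(outcome, main = character(), interactions = character(),
                       refs = list(), include_exposure = TRUE) {
  bad <- setdiff(interactions, main)
  if (length(bad)) {
    stop("interaction factors missing from main effects: ",
         paste(bad, collapse = ", "))
  }
  if (length(interactions) && !include_exposure) {
    stop("exposure interactions require the exposure main effect")
  }
  structure(list(outcome = outcome, main = main, interactions = interactions,
                 refs = as.list(refs), include_exposure = include_exposure),
            class = "model_spec")
}

# model frame: case/control universe, releveled factors, listwise deletion
followup_frame <- function(cohort, outcome, vars, refs,
                           control = c("neither", "all")) {
  control <- match.arg(control)
  m <- cohort_meta(cohort)
  if (!outcome %in% m$outcomes) stop("unknown outcome: ", outcome)
  df <- as.data.frame(cohort)
  st <- case_control_status(df, outcome, m$outcomes, control)
  df <- df[!is.na(st), , drop = FALSE]
  dat <- data.frame(.y = as.integer(st[!is.na(st)]))
  dat$.exposure <- factor(df[[m$exposure]],
                          levels = c(m$reference_level, m$index_level))
  for (f in vars) {
    fd <- m$catalog[[f]]
    if (is.null(fd)) stop("unknown factor in model: ", f)
    ref <- refs[[f]] %||% fd$levels[1L]
    if (!ref %in% fd$levels) {
      stop("reference '", ref, "' is not a level of factor '", f, "'")
    }
    dat[[f]] <- stats::relevel(factor(df[[f]], levels = fd$levels), ref = ref)
  }
  keep <- stats::complete.cases(dat)
  out <- dat[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

followup_formula <- function(spec) {
  terms <- c(if (spec$include_exposure) ".exposure", spec$main,
             if (length(spec$interactions))
               paste0(".exposure:", spec$interactions))
  stats::reformulate(if (length(terms)) terms else "1", response = ".y")
}

#' Fit a follow-up logistic model
#'
#' Maximum-likelihood logistic regression (IRLS, relative deviance change
#' below 1e-8 within 100 iterations) of the outcome on the specified terms,
#' on the outcome's case/control universe with listwise deletion of rows
#' missing any model variable. Reports exponentiated coefficients with Wald
#' 95% intervals, the AIC, and a likelihood-ratio test against the
#' intercept-only model fitted on the same rows.
#'
#' @param cohort A `cohort_table`.
#' @param spec A [model_spec()].
#' @param control Control-group rule, as in [crosstab()].
#' @param level CI coverage.
#' @return A `fit_result`: list with `coef` (term, estimate, or, ci, p),
#'   `loglik`, `aic`, `null_loglik`, `lr_stat`, `lr_df`, `lr_p`, `n`,
#'   `n_dropped`, `converged`, `separation`, and the `glm` object (`model`).
#' @export
fit_logistic <- function(cohort, spec, control = c("neither", "all"),
                         level = 0.95) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(spec, "model_spec"))
  dat <- followup_frame(cohort, spec$outcome, spec$main, spec$refs, control)
  fit_logistic_frame(dat, spec, level)
}

fit_logistic_frame <- function(dat, spec, level = 0.95) {
  fml <- followup_formula(spec)
  fit <- stats::glm(fml, family = stats::binomial(), data = dat,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  aliased <- is.na(stats::coef(fit))
  if (any(aliased)) {
    stop("rank-deficient design; aliased terms: ",
         paste(names(stats::coef(fit))[aliased], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  coef_tab <- data.frame(
    term = rownames(sm), estimate = sm[, 1L], se = sm[, 2L],
    or = exp(sm[, 1L]),
    ci_low = exp(sm[, 1L] - z * sm[, 2L]),
    ci_high = exp(sm[, 1L] + z * sm[, 2L]),
    p = sm[, 4L], row.names = NULL)
  ll <- as.numeric(stats::logLik(fit))
  null_fit <- stats::glm(.y ~ 1, family = stats::binomial(), data = dat)
  ll0 <- as.numeric(stats::logLik(null_fit))
  lr <- 2 * (ll - ll0)
  df_lr <- length(stats::coef(fit)) - 1L
  # perfectly separated fits drift to huge coefficients with huge SEs
  separation <- !fit$converged ||
    any(abs(sm[, 1L]) > 15 & sm[, 2L] > 100)
  structure(list(coef = coef_tab, loglik = ll, aic = stats::AIC(fit),
                 null_loglik = ll0, lr_stat = lr, lr_df = df_lr,
                 lr_p = if (df_lr > 0) stats::pchisq(lr, df_lr,
                                                     lower.tail = FALSE) else 1,
                 n = nrow(dat), n_dropped = attr(dat, "n_dropped") %||% 0L,
                 converged = fit$converged, separation = separation,
                 spec = spec, model = fit),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Logistic follow-up model for '", x$spec$outcome, "' (n = ", x$n,
      ")\n  AIC ", formatC(x$aic, digits = 6, format = "g"),
      ", LR vs intercept-only: X2 = ",
      formatC(x$lr_stat, digits = 4, format = "g"), " on ", x$lr_df,
      " df, p = ", format.pval(x$lr_p, digits = 3), "\n", sep = "")
  tab <- x$coef
  tab[c("estimate", "se", "or", "ci_low", "ci_high")] <-
    lapply(tab[c("estimate", "se", "or", "ci_low", "ci_high")], round, 3)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio test of a fitted model against the intercept-only model
#'
#' `LR = 2 (loglik_model - loglik_null)` referred to a chi-square with
#' degrees of freedom equal to the difference in parameter counts. Both
#' log-likelihoods come from the same rows by construction of
#' [fit_logistic()].
#'
#' @param fit A `fit_result`.
#' @return A list `(stat, df, p)`.
#' @export
lr_test_vs_null <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  list(stat = fit$lr_stat, df = fit$lr_df,
       p = if (fit$lr_df > 0)
         stats::pchisq(fit$lr_stat, fit$lr_df, lower.tail = FALSE) else 1)
}

# candidate terms are factor names ("f") and interaction labels ("f:exposure")
parse_candidates <- function(candidates) {
  inter <- grepl(":", candidates, fixed = TRUE)
  list(main = candidates[!inter],
       inter = sub(":.*$", "", candidates[inter]))
}

# unvalidated spec builder: with hierarchy disabled an orphan interaction is
# a legal (estimable) model, so model_spec()'s hierarchy check is bypassed
spec_from_terms <- function(outcome, terms, refs, include_exposure = TRUE) {
  pc <- parse_candidates(terms)
  structure(list(outcome = outcome, main = pc$main, interactions = pc$inter,
                 refs = as.list(refs), include_exposure = include_exposure),
            class = "model_spec")
}

# moves allowed under the interaction hierarchy
eligible_adds <- function(current, candidates, hierarchy) {
  pool <- setdiff(candidates, current)
  if (!hierarchy) return(pool)
  pc <- parse_candidates(pool)
  keep <- !grepl(":", pool, fixed = TRUE) |
    sub(":.*$", "", pool) %in% parse_candidates(current)$main
  pool[keep]
}

eligible_drops <- function(current, hierarchy) {
  if (!hierarchy) return(current)
  inter_factors <- parse_candidates(current)$inter
  keep <- grepl(":", current, fixed = TRUE) | !(current %in% inter_factors)
  current[keep]
}

#' Greedy AIC stepwise selection over factor and interaction terms
#'
#' Candidate terms are factor names (main effects) and
#' `"factor:exposure"` labels (exposure interactions). At each step every
#' eligible single-term addition (forward), removal (backward), or either
#' (bidirectional) is fitted and the move with the lowest resulting AIC is
#' taken if it improves on the current AIC; ties go to the earlier
#' candidate in declaration order. By default the interaction hierarchy is
#' enforced: an interaction may enter only while its main effect is in the
#' model, and a main effect may leave only after its interactions
#' (disable with `hierarchy = FALSE`). All fits use one model frame built
#' from every candidate variable (listwise deletion over the union), so
#' AICs are comparable across the whole lattice.
#'
#' @param cohort A `cohort_table`.
#' @param outcome Outcome column name.
#' @param candidates Character vector of candidate terms, in declaration
#'   order.
#' @param direction `"forward"`, `"backward"` or `"both"`.
#' @param refs Reference levels per factor.
#' @param hierarchy Enforce the interaction hierarchy (default `TRUE`).
#' @param control Control-group rule.
#' @return A list: `terms` (selected), `fit` (final `fit_result`), and
#'   `trace` (data.frame of step, action, term, AIC).
#' @export
stepwise_select <- function(cohort, outcome, candidates,
                            direction = c("forward", "backward", "both"),
                            refs = list(), hierarchy = TRUE,
                            control = c("neither", "all")) {
  direction <- match.arg(direction)
  stopifnot(length(candidates) > 0)
  all_main <- unique(c(parse_candidates(candidates)$main,
                       parse_candidates(candidates)$inter))
  dat <- followup_frame(cohort, outcome, all_main, refs,
                        match.arg(control))
  fit_terms <- function(terms) {
    sp <- spec_from_terms(outcome, terms, refs)
    tryCatch(fit_logistic_frame(dat, sp),
             error = function(e) NULL,
             warning = function(w) suppressWarnings(fit_logistic_frame(dat, sp)))
  }
  current <- switch(direction, forward = character(),
                    backward = candidates, both = character())
  cur_fit <- fit_terms(current)
  if (is.null(cur_fit)) stop("starting model failed to fit")
  trace <- data.frame(step = 0L, action = "start",
                      term = NA_character_, aic = cur_fit$aic)
  step_i <- 0L
  repeat {
    moves <- list()
    if (direction %in% c("forward", "both")) {
      for (tm in eligible_adds(current, candidates, hierarchy)) {
        moves[[length(moves) + 1L]] <- list(action = "add", term = tm,
                                            terms = c(current, tm))
      }
    }
    if (direction %in% c("backward", "both")) {
      for (tm in eligible_drops(current, hierarchy)) {
        moves[[length(moves) + 1L]] <- list(action = "drop", term = tm,
                                            terms = setdiff(current, tm))
      }
    }
    if (!length(moves)) break
    aics <- rep(NA_real_, length(moves))
    fits <- vector("list", length(moves))
    for (k in seq_along(moves)) {
      fits[[k]] <- fit_terms(moves[[k]]$terms)
      if (is.null(fits[[k]])) {
        warning("skipping non-convergent candidate move: ",
                moves[[k]]$action, " ", moves[[k]]$term)
      } else {
        aics[k] <- fits[[k]]$aic
      }
    }
    if (all(is.na(aics)) || min(aics, na.rm = TRUE) >= cur_fit$aic - 1e-10) break
    k <- which.min(aics)     # first minimum = declaration-order tie-break
    current <- moves[[k]]$terms
    cur_fit <- fits[[k]]
    step_i <- step_i + 1L
    trace <- rbind(trace, data.frame(step = step_i,
                                     action = moves[[k]]$action,
                                     term = moves[[k]]$term,
                                     aic = cur_fit$aic))
  }
  list(terms = current, fit = cur_fit, trace = trace)
}

#' Exhaustive AIC search over the candidate-term lattice
#'
#' Fits every subset of the candidate terms that respects the interaction
#' hierarchy and returns the AIC-optimal one. Exponential in the number of
#' candidates — a brute-force reference for small lattices.
#'
#' @inheritParams stepwise_select
#' @return A list: `terms`, `fit`, and `aic_table` (subset, AIC).
#' @export
exhaustive_aic <- function(cohort, outcome, candidates, refs = list(),
                           hierarchy = TRUE, control = c("neither", "all")) {
  stopifnot(length(candidates) <= 16L)
  all_main <- unique(c(parse_candidates(candidates)$main,
                       parse_candidates(candidates)$inter))
  dat <- followup_frame(cohort, outcome, all_main, refs, match.arg(control))
  nsub <- 2^length(candidates)
  best <- NULL; best_terms <- NULL
  tab <- data.frame(subset = character(nsub), aic = NA_real_)
  for (s in seq_len(nsub) - 1L) {
    terms <- candidates[bitwAnd(s, 2^(seq_along(candidates) - 1L)) > 0]
    if (hierarchy) {
      pc <- parse_candidates(terms)
      if (!all(pc$inter %in% pc$main)) next
    }
    f <- tryCatch(fit_logistic_frame(dat,
           spec_from_terms(outcome, terms, refs)),
           error = function(e) NULL)
    if (is.null(f)) next
    tab$subset[s + 1L] <- paste(terms, collapse = " + ")
    tab$aic[s + 1L] <- f$aic
    if (is.null(best) || f$aic < best$aic) {
      best <- f; best_terms <- terms
    }
  }
  list(terms = best_terms, fit = best, aic_table = tab[!is.na(tab$aic), ])
}
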