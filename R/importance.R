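#' Bias-corrected Cramér's V between two categorical vectors
#'
#' Bergsma's bias-corrected version: the chi-square based phi-squared is
#' shrunk by its expectation under independence, as are the effective table
#' dimensions, before normalisation. Pairwise-complete observations only.
#'
#' @param x,y Vectors coercible to factors.
#' @return A value in `[0, 1]` (`NA` if fewer than 2 usable observations or a
#'   degenerate margin).
#' @export
cramers_v <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- factor(x[ok]); y <- factor(y[ok])
  n <- length(x)
  r <- nlevels(droplevels(x)); k <- nlevels(droplevels(y))
  if (n < 2L || r < 2L || k < 2L) return(NA_real_)
  tab <- table(droplevels(x), droplevels(y))
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  phi2 <- unname(chi2) / n
  phi2c <- max(0, phi2 - (r - 1) * (k - 1) / (n - 1))
  rc <- r - (r - 1)^2 / (n - 1)
  kc <- k - (k - 1)^2 / (n - 1)
  denom <- min(rc - 1, kc - 1)
  if (denom <= 0) return(NA_real_)
  sqrt(phi2c / denom)
}

#' Drop one factor from each highly associated pair
#'
#' Computes the pairwise bias-corrected Cramér's V matrix over all catalogue
#' factors and greedily resolves every pair above the threshold by dropping
#' the factor with more levels (tie: the one later in catalogue order).
#' Pairs are processed in catalogue order and pairs involving an already
#' dropped factor are skipped, so mutually duplicated triples lose exactly
#' two members.
#'
#' @param cohort A `cohort_table`.
#' @param threshold Association threshold in `(0, 1]` (default 0.9).
#' @return A list: `retained` (factor names), `dropped`
#'   (data.frame `factor, because_of, v`), and `matrix` (the full V matrix,
#'   for correlation-plot style output).
#' @export
correlation_filter <- function(cohort, threshold = 0.9) {
  stopifnot(inherits(cohort, "cohort_table"), threshold > 0, threshold <= 1)
  m <- cohort_meta(cohort)
  fn <- names(m$catalog)
  p <- length(fn)
  V <- matrix(NA_real_, p, p, dimnames = list(fn, fn))
  diag(V) <- 1
  for (i in seq_len(p - 1L)) {
    for (j in seq(i + 1L, p)) {
      V[i, j] <- V[j, i] <- cramers_v(cohort[[fn[i]]], cohort[[fn[j]]])
    }
  }
  nlv <- level_counts(m$catalog)
  dropped <- character(); because <- character(); vs <- numeric()
  for (i in seq_len(p - 1L)) {
    for (j in seq(i + 1L, p)) {
      if (fn[i] %in% dropped || fn[j] %in% dropped) next
      v <- V[i, j]
      if (!is.na(v) && v > threshold) {
        # drop the factor with more levels; tie -> later in catalogue order
        loser <- if (nlv[[fn[i]]] > nlv[[fn[j]]]) fn[i] else fn[j]
        dropped <- c(dropped, loser)
        because <- c(because, setdiff(c(fn[i], fn[j]), loser))
        vs <- c(vs, v)
      }
    }
  }
  list(retained = setdiff(fn, dropped),
       dropped = data.frame(factor = dropped, because_of = because, v = vs),
       matrix = V)
}

#' Forest hyperparameters and search grid
#'
#' `nodesize` (minimum terminal-node size), `nsplit` (random split points
#' tried per candidate factor) and `mtry` (candidate factors per split) are
#' searched over a grid; the configuration with the lowest out-of-bag (OOB)
#' misclassification error wins, ties resolved towards smaller `nodesize`,
#' then smaller `mtry`. Training uses a `train_fraction` split (default
#' 80/20); the held-out fraction gives an additional test error.
#'
#' @param n_trees Trees per forest (default 500).
#' @param nodesize,nsplit,mtry Grids (non-empty numeric vectors).
#' @param train_fraction Fraction of rows used for training, in (0, 1).
#' @param seed Integer master seed; the split, each grid fit and the
#'   importance permutations draw from substreams derived from it.
#' @param split_seed Optional separate seed for the train/test split
#'   (default: derived from `seed`). Fixing it while varying `seed` isolates
#'   the Monte-Carlo (bootstrap/permutation) variability of the ensemble
#'   from the split variability.
#' @return A `forest_config`.
#' @export
forest_config <- function(n_trees = 500L,
                          nodesize = c(5L, 10L, 20L),
                          nsplit = c(1L, 2L, 5L),
                          mtry = c(3L, 5L),
                          train_fraction = 0.8, seed = 1L,
                          split_seed = NULL) {
  stopifnot(length(nodesize) > 0, length(nsplit) > 0, length(mtry) > 0,
            train_fraction > 0, train_fraction < 1, n_trees >= 1)
  structure(list(n_trees = as.integer(n_trees),
                 nodesize = as.integer(nodesize),
                 nsplit = as.integer(nsplit), mtry = as.integer(mtry),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 split_seed = if (!is.null(split_seed))
                   as.integer(split_seed)),
            class = "forest_config")
}

# deterministic substream seeds below 2^31
substream <- function(seed, k) (as.double(seed) * 7919 + 104729 * k) %% 2147483647

#' Fit a random-forest classifier with an OOB hyperparameter search
#'
#' Grows an ensemble of randomized trees (extremely-randomized split-point
#' selection, `nsplit` candidate cut points per factor) on bootstrap samples
#' of the training split, predicting a binary outcome from the catalogue
#' factors. Rows with a missing value in any used column are omitted, not
#' imputed. Every grid point is scored by OOB misclassification error; the
#' best configuration (ties: smaller `nodesize`, then smaller `mtry`) is
#' returned with its fitted ensemble, permutation importances and grid
#' table.
#'
#' @param cohort A `cohort_table`.
#' @param outcome Binary outcome column (`"yes"`/`"no"`).
#' @param cfg A [forest_config()].
#' @param factors Predictor factors (default: all catalogue factors, e.g.
#'   after [correlation_filter()]).
#' @param include_exposure Also use the exposure column as a predictor
#'   (default `FALSE`: the triage asks which factors predict the disease,
#'   irrespective of exposure).
#' @return A `forest_fit`: list with the `ranger` ensemble (`fit`),
#'   `oob_error`, `test_error`, `grid` (per-configuration OOB errors),
#'   `best` (chosen hyperparameters), index vectors of the split, and the
#'   predictor names.
#' @export
fit_forest <- function(cohort, outcome, cfg = forest_config(),
                       factors = NULL, include_exposure = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(cfg, "forest_config"))
  m <- cohort_meta(cohort)
  if (!outcome %in% m$outcomes) stop("unknown outcome: ", outcome)
  factors <- factors %||% names(m$catalog)
  cols <- c(factors, if (include_exposure) m$exposure)
  df <- as.data.frame(cohort)[c(outcome, cols)]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df[[outcome]])) < 2L) {
    stop("outcome '", outcome, "' has a single class after omitting missing rows")
  }
  for (f in factors) {
    df[[f]] <- factor(df[[f]], levels = m$catalog[[f]]$levels)
  }
  if (include_exposure) df[[m$exposure]] <- factor(df[[m$exposure]])
  df[[outcome]] <- factor(df[[outcome]], levels = c("no", "yes"))

  set.seed(substream(cfg$split_seed %||% cfg$seed, 0L))
  n <- nrow(df)
  train_idx <- sort(sample.int(n, round(cfg$train_fraction * n)))
  test_idx <- setdiff(seq_len(n), train_idx)
  train <- df[train_idx, , drop = FALSE]

  grid <- expand.grid(nodesize = cfg$nodesize, nsplit = cfg$nsplit,
                      mtry = cfg$mtry, KEEP.OUT.ATTRS = FALSE)
  grid$mtry <- pmin(grid$mtry, length(cols))
  grid <- unique(grid)
  fits <- vector("list", nrow(grid))
  grid$oob_error <- NA_real_
  fml <- stats::as.formula(paste(outcome, "~ ."))
  for (g in seq_len(nrow(grid))) {
    fits[[g]] <- ranger::ranger(
      fml, data = train, num.trees = cfg$n_trees,
      mtry = grid$mtry[g], min.node.size = grid$nodesize[g],
      splitrule = "extratrees", num.random.splits = grid$nsplit[g],
      importance = "permutation", scale.permutation.importance = FALSE,
      respect.unordered.factors = "ignore",
      seed = substream(cfg$seed, g), num.threads = 1L)
    grid$oob_error[g] <- fits[[g]]$prediction.error
  }
  ord <- order(grid$oob_error, grid$nodesize, grid$mtry)
  best <- ord[1L]
  fit <- fits[[best]]
  pred <- stats::predict(fit, df[test_idx, , drop = FALSE],
                         num.threads = 1L)$predictions
  test_error <- if (length(test_idx)) {
    mean(as.character(pred) != as.character(df[[outcome]][test_idx]))
  } else NA_real_
  structure(list(fit = fit, oob_error = grid$oob_error[best],
                 test_error = test_error, grid = grid,
                 best = grid[best, c("nodesize", "nsplit", "mtry")],
                 train_idx = train_idx, test_idx = test_idx,
                 factors = cols, outcome = outcome, config = cfg),
            class = "forest_fit")
}

#' @export
print.forest_fit <- function(x, ...) {
  cat("Random forest for '", x$outcome, "': ", x$config$n_trees,
      " trees, OOB error ", formatC(x$oob_error, digits = 4, format = "g"),
      "\n  best: nodesize=", x$best$nodesize, " nsplit=", x$best$nsplit,
      " mtry=", x$best$mtry, "\n", sep = "")
  invisible(x)
}

#' Permutation variable importance (VIMP)
#'
#' Per factor: the average over trees of the increase in OOB prediction
#' error after permuting the factor's out-of-bag values. Positive VIMP
#' marks informative factors; values near zero or negative mark presumable
#' noise. A factor never used by any tree scores exactly 0.
#'
#' @param ffit A `forest_fit`.
#' @return Named numeric vector of signed importances, decreasing.
#' @export
vimp <- function(ffit) {
  stopifnot(inherits(ffit, "forest_fit"))
  sort(ffit$fit$variable.importance, decreasing = TRUE)
}

#' Mean minimal depth of each factor
#'
#' A factor's minimal depth in a tree is the depth (root = 0) of the
#' shallowest node splitting on it; factors that partition large sample
#' fractions split early and get low values. A factor absent from a tree is
#' assigned that tree's maximal depth + 1 — deeper than anything actually
#' used. Values are averaged over trees.
#'
#' The selection threshold (the "dashed line") is the mean of the per-factor
#' mean minimal depths: under uninformative ordering no factor is expected
#' to beat the average, so factors below it are flagged as selected.
#'
#' @param ffit A `forest_fit`.
#' @return A list: `depth` (named numeric, increasing), `threshold`, and
#'   `selected` (factors with mean depth below the threshold).
#' @export
minimal_depth <- function(ffit) {
  stopifnot(inherits(ffit, "forest_fit"))
  vars <- ffit$fit$forest$independent.variable.names
  ntree <- ffit$fit$num.trees
  acc <- matrix(NA_real_, ntree, length(vars), dimnames = list(NULL, vars))
  for (t in seq_len(ntree)) {
    ti <- ranger::treeInfo(ffit$fit, t)
    depth <- rep(NA_real_, nrow(ti))
    depth[1L] <- 0
    # ranger child ids always exceed the parent id: one ordered pass
    for (r in seq_len(nrow(ti))) {
      if (!ti$terminal[r]) {
        depth[ti$leftChild[r] + 1L] <- depth[r] + 1
        depth[ti$rightChild[r] + 1L] <- depth[r] + 1
      }
    }
    maxd <- max(depth)
    md <- tapply(depth[!ti$terminal], ti$splitvarName[!ti$terminal], min)
    row <- rep(maxd + 1, length(vars))
    names(row) <- vars
    row[names(md)] <- md
    acc[t, ] <- row
  }
  mean_depth <- sort(colMeans(acc))
  threshold <- mean(mean_depth)
  list(depth = mean_depth, threshold = threshold,
       selected = names(mean_depth)[mean_depth < threshold])
}

#' Importance summary table
#'
#' Combines VIMP and minimal depth into one table per factor, with the
#' minimal-depth selection flag.
#'
#' @param ffit A `forest_fit`.
#' @return A data.frame `(factor, vimp, min_depth, selected)` ordered by
#'   decreasing VIMP.
#' @export
importance_table <- function(ffit) {
  v <- vimp(ffit)
  md <- minimal_depth(ffit)
  out <- data.frame(factor = names(v), vimp = unname(v),
                    min_depth = unname(md$depth[names(v)]),
                    selected = names(v) %in% md$selected)
  attr(out, "min_depth_threshold") <- md$threshold
  out
}
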