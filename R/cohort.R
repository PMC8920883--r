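#' Construct a validated cohort table
#'
#' A cohort table is one row per subject: a unique subject id, a binary
#' exposure column (index vs reference arm, e.g. low vs high socioeconomic
#' status), one or more binary outcome columns coded `"yes"`/`"no"`, and one
#' column per catalogue factor holding a declared level label or `NA`.
#'
#' Exposure orientation is explicit configuration: `index_level` names the arm
#' whose odds appear in the numerator of every screened odds ratio, so OR > 1
#' always means higher odds in the index arm. It is never inferred from label
#' sort order.
#'
#' @param data A data.frame with the columns below.
#' @param catalog The `factor_catalog` describing the factor columns.
#' @param id Name of the subject-id column.
#' @param exposure Name of the exposure column.
#' @param index_level,reference_level Exposure labels for the index and
#'   reference arms.
#' @param outcomes Character vector of outcome column names (values
#'   `"yes"`/`"no"`/`NA`).
#' @param strict If `TRUE`, require exposure in `{index, reference}` and all
#'   outcomes non-missing (the state after [apply_exclusions()]); if `FALSE`
#'   (default) other exposure labels and missing outcomes are tolerated so raw
#'   files can be loaded before exclusion rules run.
#' @return A `cohort_table`: the data.frame with validation applied and the
#'   design metadata stored as attributes.
#' @export
cohort_table <- function(data, catalog, id = "subject_id",
                         exposure = "exposure",
                         index_level, reference_level,
                         outcomes, strict = FALSE) {
  stopifnot(is.data.frame(data), inherits(catalog, "factor_catalog"))
  need <- c(id, exposure, outcomes, names(catalog))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  ids <- data[[id]]
  if (anyDuplicated(ids)) {
    stop("duplicate subject_id values: ",
         paste(utils::head(unique(ids[duplicated(ids)]), 5L), collapse = ", "))
  }
  for (f in catalog) {
    vals <- as.character(data[[f$name]])
    bad <- !is.na(vals) & !(vals %in% f$levels)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("row ", i, ", column '", f$name, "': value '", vals[i],
           "' is not a declared level")
    }
    data[[f$name]] <- vals
  }
  for (oc in outcomes) {
    v <- as.character(data[[oc]])
    bad <- !is.na(v) & !(v %in% c("yes", "no"))
    if (any(bad)) {
      stop("outcome '", oc, "' has values outside yes/no: ",
           paste(utils::head(unique(v[bad]), 3L), collapse = ", "))
    }
    data[[oc]] <- v
  }
  data[[exposure]] <- as.character(data[[exposure]])
  if (strict) {
    ex <- data[[exposure]]
    if (anyNA(ex) || !all(ex %in% c(index_level, reference_level))) {
      stop("strict cohort: exposure must be '", index_level, "' or '",
           reference_level, "' with no missing values")
    }
    for (oc in outcomes) {
      if (anyNA(data[[oc]])) stop("strict cohort: outcome '", oc, "' has missing values")
    }
  }
  structure(data,
            class = c("cohort_table", "data.frame"),
            catalog = catalog, id = id, exposure = exposure,
            index_level = index_level, reference_level = reference_level,
            outcomes = outcomes)
}

cohort_meta <- function(cohort) {
  attributes(cohort)[c("catalog", "id", "exposure", "index_level",
                       "reference_level", "outcomes")]
}

rebuild_cohort <- function(data, meta, strict = FALSE) {
  cohort_table(as.data.frame(data), meta$catalog, id = meta$id,
               exposure = meta$exposure, index_level = meta$index_level,
               reference_level = meta$reference_level,
               outcomes = meta$outcomes, strict = strict)
}

#' @export
print.cohort_table <- function(x, ...) {
  m <- cohort_meta(x)
  cat("Cohort table: ", nrow(x), " subjects, ",
      length(m$catalog), " factors, outcomes: ",
      paste(m$outcomes, collapse = ", "), "\n", sep = "")
  cat("Exposure '", m$exposure, "': index = ", m$index_level,
      ", reference = ", m$reference_level, "\n", sep = "")
  NextMethod()
}

#' Read a cohort CSV
#'
#' Reads a UTF-8, comma-separated, headered file, one row per subject.
#' Empty strings and the literal `NA` are treated as missing (extendable via
#' `na_tokens`). Columns can be renamed on the way in through `column_map`
#' (`c(canonical = "file_column")`); file columns mapped to nothing are kept
#' only if they are declared cohort columns, otherwise they are dropped with
#' one warning naming them.
#'
#' @inheritParams cohort_table
#' @param path CSV file path.
#' @param column_map Optional named character vector renaming file columns to
#'   canonical names.
#' @param na_tokens Strings read as missing.
#' @return A `cohort_table`, rows in file order.
#' @export
read_cohort <- function(path, catalog, id = "subject_id",
                        exposure = "exposure",
                        index_level, reference_level, outcomes,
                        column_map = NULL, na_tokens = c("", "NA"),
                        strict = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = na_tokens, check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(df))
    if (length(missing_src)) {
      stop("column_map names absent from file: ",
           paste(missing_src, collapse = ", "))
    }
    idx <- match(unname(column_map), names(df))
    names(df)[idx] <- names(column_map)
  }
  declared <- c(id, exposure, outcomes, names(catalog))
  extra <- setdiff(names(df), declared)
  if (length(extra)) {
    warning("ignoring ", length(extra), " unmapped column(s): ",
            paste(extra, collapse = ", "))
    df <- df[declared[declared %in% names(df)]]
  }
  cohort_table(df, catalog, id = id, exposure = exposure,
               index_level = index_level, reference_level = reference_level,
               outcomes = outcomes, strict = strict)
}

#' Write a cohort table to CSV
#'
#' Missing values are written as empty fields, so a write/read round trip
#' reproduces the table exactly.
#'
#' @param cohort A `cohort_table`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Exclusion rules for a raw cohort
#'
#' Mirrors the usual survey clean-up: drop subjects in exposure arms outside
#' the binary contrast (e.g. a medium stratum when only low vs high is
#' compared), drop subjects missing any of the listed columns (outcomes,
#' exposure), and optionally drop by a predicate on one column (e.g. an age
#' band where the diagnosis is unreliable).
#'
#' @param drop_exposure_levels Raw exposure labels whose rows are removed.
#' @param drop_if_missing Column names whose missingness removes the row.
#' @param drop_filter Optional predicate `function(values) -> logical`
#'   (`TRUE` = drop) applied to `drop_filter_column`.
#' @param drop_filter_column Column the predicate reads.
#' @return An `exclusion_config`.
#' @export
exclusion_config <- function(drop_exposure_levels = character(),
                             drop_if_missing = character(),
                             drop_filter = NULL, drop_filter_column = NULL) {
  if (!is.null(drop_filter)) {
    stopifnot(is.function(drop_filter), is.character(drop_filter_column))
  }
  structure(list(drop_exposure_levels = as.character(drop_exposure_levels),
                 drop_if_missing = as.character(drop_if_missing),
                 drop_filter = drop_filter,
                 drop_filter_column = drop_filter_column),
            class = "exclusion_config")
}

#' Apply exclusion rules to a cohort
#'
#' Rules are applied jointly (a row is kept iff it passes all of them), but
#' the removal tally attributes each dropped row to the first rule, in
#' declared order, that it fails: exposure-level drops, then each
#' missing-column rule in order, then the predicate filter. The tally is
#' therefore deterministic and its entries sum to `rows_in - rows_out`.
#'
#' @param cohort A `cohort_table`.
#' @param cfg An `exclusion_config`.
#' @return A list with `cohort` (the filtered table, validated strictly when
#'   exposure and outcomes are fully resolved) and `tally` (named integer of
#'   rows removed per rule).
#' @export
apply_exclusions <- function(cohort, cfg) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(cfg, "exclusion_config"))
  m <- cohort_meta(cohort)
  df <- as.data.frame(cohort)
  bad <- setdiff(cfg$drop_if_missing, names(df))
  if (length(bad)) stop("drop_if_missing columns not in cohort: ",
                        paste(bad, collapse = ", "))
  n <- nrow(df)
  attributed <- rep(NA_character_, n)
  rules <- character()

  note <- function(rule, hit) {
    rules <<- c(rules, rule)
    take <- hit & is.na(attributed)
    attributed[take] <<- rule
  }
  if (length(cfg$drop_exposure_levels)) {
    note("exposure_level", df[[m$exposure]] %in% cfg$drop_exposure_levels)
  }
  for (col in cfg$drop_if_missing) {
    note(paste0("missing_", col), is.na(df[[col]]))
  }
  if (!is.null(cfg$drop_filter)) {
    if (!cfg$drop_filter_column %in% names(df)) {
      stop("drop_filter_column not in cohort: ", cfg$drop_filter_column)
    }
    hit <- cfg$drop_filter(df[[cfg$drop_filter_column]])
    hit[is.na(hit)] <- FALSE
    note(paste0("filter_", cfg$drop_filter_column), hit)
  }
  keep <- is.na(attributed)
  tally <- if (length(rules)) {
    tab <- table(factor(attributed, levels = rules))
    stats::setNames(as.integer(tab), rules)
  } else stats::setNames(integer(0), character(0))

  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  strict <- !anyNA(out[[m$exposure]]) &&
    all(out[[m$exposure]] %in% c(m$index_level, m$reference_level)) &&
    !any(vapply(m$outcomes, function(oc) anyNA(out[[oc]]), logical(1L)))
  list(cohort = rebuild_cohort(out, m, strict = strict), tally = tally)
}

#' Recode missing factor values to an explicit "no data" level
#'
#' Every missing factor value becomes the reserved level `"no data"`, and the
#' catalogue gains that level (once) for each affected factor. Systematic
#' missingness then stays visible in screening as its own subgroup instead of
#' silently shrinking the others. Exposure and outcome missingness must have
#' been resolved by [apply_exclusions()] before this step.
#'
#' @param cohort A `cohort_table`.
#' @return A list with the recoded `cohort` and the updated `catalog`.
#' @export
recode_missing_to_nodata <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  m <- cohort_meta(cohort)
  df <- as.data.frame(cohort)
  cat2 <- m$catalog
  for (f in m$catalog) {
    v <- df[[f$name]]
    if (anyNA(v)) {
      df[[f$name]][is.na(v)] <- NODATA
      if (!f$has_nodata_level) {
        cat2[[f$name]] <- fct_def(f$name, c(f$levels, NODATA),
                                  ordered = f$ordered)
      }
    }
  }
  m$catalog <- factor_catalog(cat2)
  list(cohort = rebuild_cohort(df, m), catalog = m$catalog)
}

#' Bin a numeric column into ordered categories
#'
#' Intervals are right-closed: value `v` gets label `i` when
#' `cut_points[i-1] < v <= cut_points[i]`, with open-ended extremes, so a
#' value exactly at a cut point falls in the lower bin. Missing values stay
#' missing.
#'
#' @param values Numeric vector (or character coercible to numeric).
#' @param cut_points Strictly ascending numeric cut points.
#' @param labels Labels, one more than there are cut points.
#' @return Character vector of labels, same length as `values`.
#' @export
#' @examples
#' bin_numeric_column(c(3, 24, 25, 40), c(24, 29), c("<=24", "25-29", ">=30"))
bin_numeric_column <- function(values, cut_points, labels) {
  stopifnot(length(labels) == length(cut_points) + 1L)
  if (length(cut_points) && is.unsorted(cut_points, strictly = TRUE)) {
    stop("cut_points must be strictly ascending")
  }
  if (length(values) == 0L) return(character(0))
  num <- suppressWarnings(as.numeric(values))
  bad <- is.na(num) & !is.na(values)
  if (any(bad)) stop("non-numeric value at index ", which(bad)[1L])
  idx <- findInterval(num, cut_points, left.open = TRUE) + 1L
  out <- labels[idx]
  out[is.na(num)] <- NA_character_
  as.character(out)
}
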