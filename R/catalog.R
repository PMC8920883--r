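#' Define a categorical screening factor
#'
#' A factor is a named categorical variable with a declared, ordered list of
#' level labels. Trend (interaction-plot) analysis is only meaningful for
#' ordered factors, so the ordering flag is carried explicitly rather than
#' inferred. The reserved level label `"no data"` marks the explicit
#' missing-value category created by [recode_missing_to_nodata()]; it is
#' excluded from trend sequences.
#'
#' @param name Factor name (single non-empty string).
#' @param levels Character vector of distinct level labels (at least one).
#' @param ordered Logical; `TRUE` if the declared level order is substantive
#'   (ordinal scale) so trends across levels can be read.
#' @return An object of class `fct_def`.
#' @export
#' @examples
#' fct_def("age_group", c("4-6", "7-10", "11-13", "14-17"), ordered = TRUE)
fct_def <- function(name, levels, ordered = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (length(levels) < 1L) stop("factor '", name, "' needs at least one level")
  if (anyDuplicated(levels)) {
    stop("factor '", name, "' has duplicated level labels: ",
         paste(unique(levels[duplicated(levels)]), collapse = ", "))
  }
  structure(
    list(name = name, levels = levels, ordered = isTRUE(ordered),
         has_nodata_level = NODATA %in% levels),
    class = "fct_def"
  )
}

NODATA <- "no data"

#' Build a factor catalogue
#'
#' The catalogue is the registry of all screening factors and the single
#' source of subgroup enumeration: every level of every factor, and every
#' cross-factor level pair, defines a subgroup.
#'
#' @param ... `fct_def` objects (or a single list of them).
#' @return An object of class `factor_catalog`: a named list of `fct_def`s.
#' @seealso [read_catalog()], [enumerate_subgroups()]
#' @export
factor_catalog <- function(...) {
  fs <- list(...)
  if (length(fs) == 1L && !inherits(fs[[1L]], "fct_def")) fs <- fs[[1L]]
  if (length(fs) == 0L) stop("catalogue must contain at least one factor")
  ok <- vapply(fs, inherits, logical(1L), what = "fct_def")
  if (!all(ok)) stop("all catalogue entries must be fct_def objects")
  nms <- vapply(fs, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) {
    stop("duplicated factor names in catalogue: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(fs) <- nms
  structure(fs, class = "factor_catalog")
}

#' @export
print.factor_catalog <- function(x, ...) {
  cat("Factor catalogue: ", length(x), " factors, ",
      total_levels(x), " levels\n", sep = "")
  for (f in x) {
    cat("  ", f$name, " (", length(f$levels),
        if (f$ordered) ", ordered" else "", "): ",
        paste(utils::head(f$levels, 6L), collapse = ", "),
        if (length(f$levels) > 6L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Per-factor level counts of a catalogue
#' @param catalog A `factor_catalog`.
#' @return Named integer vector of level counts.
#' @export
level_counts <- function(catalog) {
  stopifnot(inherits(catalog, "factor_catalog"))
  vapply(catalog, function(f) length(f$levels), integer(1L))
}

#' Total number of factor levels in a catalogue
#' @param catalog A `factor_catalog`.
#' @return Integer: the sum of per-factor level counts.
#' @export
total_levels <- function(catalog) sum(level_counts(catalog))

#' Read a factor catalogue from YAML or JSON
#'
#' The file maps factor names to `{levels: [...], ordered: bool}` entries.
#' Format is chosen by file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path Path to the catalogue file.
#' @return A `factor_catalog`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("catalogue file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported catalogue format: .", ext)
  )
  fs <- lapply(names(raw), function(nm) {
    entry <- raw[[nm]]
    fct_def(nm, unlist(entry$levels, use.names = FALSE),
            ordered = isTRUE(entry$ordered))
  })
  factor_catalog(fs)
}

#' Write a factor catalogue to YAML or JSON
#' @param catalog A `factor_catalog`.
#' @param path Destination path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "factor_catalog"))
  out <- lapply(catalog, function(f) list(levels = f$levels, ordered = f$ordered))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml  = yaml::write_yaml(out, path),
    json = writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, pretty = TRUE), path),
    stop("unsupported catalogue format: .", ext)
  )
  invisible(path)
}
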