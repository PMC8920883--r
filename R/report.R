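#' @importFrom rlang .data
NULL

#' Write screen results to CSV and JSON
#'
#' Serialises the per-subgroup records flat (subgroup key, factors/levels,
#' outcome, cell counts, point, CI, display, flags) at full precision;
#' rounding is a presentation concern. `Inf` and `NaN` survive the JSON trip
#' as the strings `"Inf"`/`"NaN"`.
#'
#' @param result A `screen_result`.
#' @param path Output path without extension; `<path>.csv` and
#'   `<path>_overall.csv` are written, plus `<path>.json` when
#'   `json = TRUE`.
#' @param json Also write JSON (default `FALSE`).
#' @return The CSV path, invisibly.
#' @export
write_screen <- function(result, path, json = FALSE) {
  stopifnot(inherits(result, "screen_result"))
  utils::write.csv(result$rows, paste0(path, ".csv"), row.names = FALSE)
  utils::write.csv(result$overall, paste0(path, "_overall.csv"),
                   row.names = FALSE)
  if (json) {
    jsonlite::write_json(list(rows = result$rows, overall = result$overall),
                         paste0(path, ".json"), dataframe = "rows",
                         na = "string", digits = NA)
  }
  invisible(paste0(path, ".csv"))
}

#' Write a run manifest
#'
#' Records the package version, seed, input-file MD5 hashes, per-stage row
#' counts and a timestamp next to a run's outputs, so any result file can be
#' traced to its exact inputs. Re-running with identical inputs reproduces
#' identical result files (the timestamp aside).
#'
#' @param dir Output directory (one manifest per directory).
#' @param seed Integer seed of the run.
#' @param inputs Character vector of input file paths to hash.
#' @param counts Named list/vector of per-stage row counts.
#' @param extra Optional named list merged into the manifest.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, seed, inputs = character(),
                           counts = list(), extra = list()) {
  manifest <- c(list(
    tool = "factorscreen",
    version = as.character(utils::packageVersion("factorscreen")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(stats::setNames(
      as.character(tools::md5sum(inputs)), basename(inputs))),
    counts = as.list(counts)), extra)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
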