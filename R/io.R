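#' Write study outputs to a directory
#'
#' Writes `trace_<mode>.csv` per mode, a combined `metrics.json`, and a
#' `manifest.json` listing every written file with its MD5 content hash.
#' Re-running on identical inputs yields identical hashes.
#'
#' @param result A `study_result` or `study_set`.
#' @param dir Output directory (created if missing).
#' @return The manifest as a tibble (`file`, `md5`), invisibly.
#' @export
write_outputs <- function(result, dir) {
  if (inherits(result, "study_result")) {
    result <- structure(stats::setNames(list(result), result$mode),
                        class = "study_set")
  }
  stopifnot(inherits(result, "study_set"))
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(sprintf("cannot create output directory %s", dir),
          class = "adaptloop_io_error")
  }
  files <- character(0)
  for (r in result) {
    f <- file.path(dir, sprintf("trace_%s.csv", r$mode))
    readr::write_csv(r$trace, f)
    files <- c(files, f)
  }
  metrics <- lapply(unclass(result), function(r) r$metrics)
  mf <- file.path(dir, "metrics.json")
  jsonlite::write_json(metrics, mf, auto_unbox = TRUE, digits = NA,
                       na = "null")
  files <- c(files, mf)
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Reload a written difficulty trace
#'
#' @param path Path to a `trace_<mode>.csv` written by [write_outputs()].
#' @return The trace tibble.
#' @export
read_trace <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    game = readr::col_integer(), mode = readr::col_character(),
    score = readr::col_double(), mean_hr = readr::col_double(),
    end_difficulty = readr::col_double()))
}
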