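# Plain-text table readers/writers for the pipeline's intermediates.
# All artifacts are tab-delimited with a header so runs are diffable.

#' Write a delimited table
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_txt <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a delimited table written by [write_table_txt()]
#'
#' @param path input path.
#' @return data.frame.
#' @export
read_table_txt <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

#' Write or read a localization table
#'
#' Columns: `frame` (0-based integer), `x_um`, `y_um`, `z_um`,
#' `intensity` and optionally the ground-truth `event_id`.
#'
#' @param locs localization table.
#' @param path file path.
#' @return The table (reader) or `path` invisibly (writer).
#' @export
write_localizations <- function(locs, path) {
  check_columns(locs, c("frame", "x_um", "y_um"), "`locs`")
  write_table_txt(locs, path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  out <- read_table_txt(path)
  check_columns(out, c("frame", "x_um", "y_um"), "localization file")
  class(out) <- c("localization_table", "data.frame")
  out
}

#' Read or write a pipeline configuration
#'
#' Configurations are nested key-value structures stored as JSON; they
#' round-trip losslessly through [write_config()] / [read_config()].
#' See [default_config()] for the full set of tunables.
#'
#' @param config a configuration list.
#' @param path file path.
#' @return The configuration list (reader) or `path` invisibly
#'   (writer).
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE,
                      simplifyDataFrame = FALSE)
}
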