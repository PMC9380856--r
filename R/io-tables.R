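#' Read / write the long-format measurements table
#'
#' CSV dialect: comma-separated, UTF-8, mandatory header, decimal point.
#' One row per (subject, rater, side); CSF columns are repeated per rater
#' and must be side-independent. Validated on both read and write.
#'
#' @param measurements data.frame, see [validate_measurements()].
#' @param path CSV file path.
#' @return `read_measurements` returns the validated data.frame;
#'   `write_measurements` returns `path` invisibly.
#' @export
write_measurements <- function(measurements, path) {
  validate_measurements(measurements)
  utils::write.csv(measurements, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_measurements(m)
  m
}

#' Read / write the per-subject indices table
#'
#' @param indices data.frame as returned by [compute_indices()].
#' @param path CSV file path.
#' @return `read_indices` returns the data.frame; `write_indices` returns
#'   `path` invisibly.
#' @export
write_indices <- function(indices, path) {
  utils::write.csv(indices, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_indices
#' @export
read_indices <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
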