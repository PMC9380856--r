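report_required_keys <- c("meta", "indices", "comparisons", "normality", "roc", "icc")

#' Write an analysis report
#'
#' Writes `report.json` (the full machine-readable report, floats at full
#' precision) plus flat CSV views: `comparisons.csv`, `icc.csv`,
#' `indices.csv`, and `roc.csv` (per-cutoff sensitivity/specificity of
#' every ROC curve, for plotting).
#'
#' @param report An `ln_report` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ln_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plain <- unclass(report)
  plain$roc <- lapply(plain$roc, unclass)
  jsonlite::write_json(plain, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"), row.names = FALSE)
  utils::write.csv(report$icc, file.path(dir, "icc.csv"), row.names = FALSE)
  utils::write.csv(report$indices, file.path(dir, "indices.csv"), row.names = FALSE)
  roc_flat <- do.call(rbind, lapply(report$roc, function(r) {
    cbind(data.frame(index = r$index_name, positive_group = r$positive_group,
                     comparison_group = r$comparison_group,
                     orientation = r$orientation, auc = r$auc,
                     stringsAsFactors = FALSE),
          r$curve)
  }))
  if (is.null(roc_flat)) {
    roc_flat <- data.frame(index = character(), positive_group = character(),
                           comparison_group = character(), orientation = character(),
                           auc = numeric(), cutoff = numeric(),
                           sensitivity = numeric(), specificity = numeric())
  }
  utils::write.csv(roc_flat, file.path(dir, "roc.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an analysis report
#'
#' Reads `report.json` back into an `ln_report`, validating that every
#' required section is present (an error names the missing key).
#'
#' @param dir Directory written by [write_report()] (or a path to a
#'   report.json).
#' @return An `ln_report`.
#' @export
read_report <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "report.json") else dir
  if (!file.exists(path)) stop("no report.json found at ", dir)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (key in report_required_keys) {
    if (is.null(raw[[key]])) stop("report schema violation: missing required key '", key, "'")
  }
  # roc is serialized as a named JSON object, one entry per analyzed index
  raw$roc <- lapply(raw$roc, function(r) {
    r$curve <- as.data.frame(r$curve)
    structure(r, class = "roc_result")
  })
  structure(raw, class = "ln_report")
}
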