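#' Full statistical analysis of a cohort
#'
#' Runs the complete battery on a long-format measurements table:
#' subject-level indices, normality-gated pairwise group comparisons for
#' all 12 indices, ROC analysis (with Youden cutoff) of every index that
#' differs significantly between the positive group and each comparison
#' group, and per-group two-rater ICCs of the side-mean indices.
#'
#' @param measurements Long-format table, see [validate_measurements()].
#' @param positive_group Group treated as positive in ROC analyses.
#' @param alpha Significance level for both the normality gate and ROC
#'   index selection.
#' @return Object of class `ln_report`: list with
#'   \describe{
#'     \item{meta}{groups, per-group n, `positive_group`, `alpha`.}
#'     \item{indices}{per-subject index table.}
#'     \item{comparisons}{data.frame `index`, `group1`, `group2`,
#'       `p_value`, `test_used`.}
#'     \item{normality}{per index x group Shapiro-Wilk p-values.}
#'     \item{roc}{list of [roc_analysis()] results for the selected
#'       indices.}
#'     \item{icc}{data.frame `group`, `index`, `icc`, `band`, `model`.}
#'   }
#' @export
run_full_analysis <- function(measurements, positive_group = "MSA-P", alpha = 0.05) {
  idx <- compute_indices(measurements)
  groups <- unique(idx$group)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (!positive_group %in% groups) stop("positive_group '", positive_group, "' not in data")
  index_cols <- c("cSL", "SL", "LL", "cSLLr", "SLLr", "Area",
                  "SIm_LN", "SIsd_LN", "cSIsd_LN", "SIm_CSF", "SIsd_CSF", "nSIm")

  cmp <- lapply(index_cols, function(nm) compare_groups(idx, nm, alpha = alpha))
  names(cmp) <- index_cols
  comparisons <- do.call(rbind, lapply(cmp, function(cc) {
    data.frame(index = cc$index_name, cc$pairs, test_used = cc$test_used,
               stringsAsFactors = FALSE)
  }))
  rownames(comparisons) <- NULL
  normality <- do.call(rbind, lapply(cmp, function(cc) {
    data.frame(index = cc$index_name, group = names(cc$shapiro_p),
               shapiro_p = unname(cc$shapiro_p), stringsAsFactors = FALSE)
  }))
  rownames(normality) <- NULL

  roc <- list()
  for (cg in setdiff(groups, positive_group)) {
    sel <- comparisons[(comparisons$group1 == positive_group & comparisons$group2 == cg) |
                       (comparisons$group1 == cg & comparisons$group2 == positive_group), ]
    for (nm in sel$index[sel$p_value < alpha]) {
      roc[[paste(nm, positive_group, "vs", cg)]] <- roc_analysis(idx, nm, positive_group, cg)
    }
  }

  ri <- rater_indices(measurements)
  icc_cols <- c("SL", "LL", "SLLr", "Area", "SIm", "SIsd", "nSIm")
  icc <- do.call(rbind, lapply(groups, function(gp) {
    rg <- ri[ri$group == gp, ]
    r1 <- rg[rg$rater == 1, ]; r2 <- rg[rg$rater == 2, ]
    stopifnot(identical(r1$subject_id, r2$subject_id))
    do.call(rbind, lapply(icc_cols, function(nm) {
      res <- tryCatch(icc_two_rater(cbind(r1[[nm]], r2[[nm]])),
                      error = function(e) NULL)
      data.frame(group = gp, index = nm,
                 icc = if (is.null(res)) NA_real_ else res$icc,
                 band = if (is.null(res)) NA_character_ else res$band,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(icc) <- NULL

  structure(list(
    meta = list(groups = as.character(groups),
                n_per_group = as.integer(table(idx$group)[as.character(groups)]),
                positive_group = positive_group, alpha = alpha,
                icc_model = "two-way random, absolute agreement, single rater (ICC(2,1))"),
    indices = idx, comparisons = comparisons, normality = normality,
    roc = roc, icc = icc),
    class = "ln_report")
}

#' @export
print.ln_report <- function(x, ...) {
  cat("Lentiform nucleus morphometry report\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", x$meta$groups, x$meta$n_per_group),
                         collapse = ", "), "\n")
  sig <- x$comparisons[x$comparisons$p_value < x$meta$alpha, ]
  cat("  significant pairwise differences:", nrow(sig), "of", nrow(x$comparisons), "\n")
  for (r in x$roc) {
    cat(sprintf("  ROC %s [%s vs %s]: AUC %.3f, cutoff %.3f (%s), sens %.3f, spec %.3f\n",
                r$index_name, r$positive_group, r$comparison_group, r$auc,
                r$cutoff, r$orientation, r$sensitivity, r$specificity))
  }
  invisible(x)
}
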