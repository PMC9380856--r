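#' ROC analysis with Youden-index cutoff
#'
#' Empirical ROC of one index for discriminating the positive group from a
#' comparison group. Orientation is chosen so that the positive group's
#' mean lies on the "positive" side of the scale (recorded as
#' `lower_is_positive` or `higher_is_positive`); if the resulting empirical
#' AUC still falls below 0.5 the orientation is flipped with a warning. The
#' AUC is the trapezoid area under the empirical curve, which equals the
#' Mann-Whitney statistic divided by `n1 * n2` (ties contribute 1/2).
#' Candidate cutoffs are the midpoints between adjacent sorted unique
#' values; the returned cutoff maximizes Youden's J = sensitivity +
#' specificity - 1, with ties broken toward the cutoff giving higher
#' sensitivity.
#'
#' @param indices data.frame with a `group` column and the index column.
#' @param index_name Column to analyze.
#' @param positive_group Group treated as positive (diseased).
#' @param comparison_group Group treated as negative.
#' @param group_col Name of the grouping column.
#' @return Object of class `roc_result`: list with `index_name`,
#'   `positive_group`, `comparison_group`, `orientation`, `auc`, `cutoff`
#'   (index units), `youden_j`, `sensitivity`, `specificity`, and `curve`
#'   (data.frame `cutoff`, `sensitivity`, `specificity` over all candidate
#'   cutoffs).
#' @export
roc_analysis <- function(indices, index_name, positive_group, comparison_group,
                         group_col = "group") {
  if (!index_name %in% names(indices)) stop("no such index column: ", index_name)
  g <- indices[[group_col]]
  pos <- indices[[index_name]][g == positive_group]
  neg <- indices[[index_name]][g == comparison_group]
  if (length(pos) < 2 || length(neg) < 2) stop("both groups need n >= 2")
  if (length(unique(c(pos, neg))) == 1L) stop("degenerate data: all values identical")

  orientation <- if (mean(pos) <= mean(neg)) "lower_is_positive" else "higher_is_positive"
  res <- roc_core(pos, neg, orientation)
  if (res$auc < 0.5) {
    warning("empirical AUC below 0.5 under the mean-based orientation; flipping")
    orientation <- setdiff(c("lower_is_positive", "higher_is_positive"), orientation)
    res <- roc_core(pos, neg, orientation)
  }
  structure(c(list(index_name = index_name, positive_group = positive_group,
                   comparison_group = comparison_group, orientation = orientation),
              res),
            class = "roc_result")
}

# scores oriented so higher = more positive; cutoffs reported in original units
roc_core <- function(pos, neg, orientation) {
  s <- if (orientation == "lower_is_positive") -1 else 1
  p <- s * pos; q <- s * neg
  u <- sort(unique(c(p, q)))
  np <- length(p); nq <- length(q)
  p_le <- findInterval(u, sort(p))   # count of positives <= u_i
  q_le <- findInterval(u, sort(q))
  # ROC points at thresholds u_i (classify positive when score > u_i),
  # plus the (1,1) endpoint; trapezoid handles tie-induced diagonals
  tpr <- c(1, (np - p_le) / np)
  fpr <- c(1, (nq - q_le) / nq)
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) * (tpr[-length(tpr)] + tpr[-1]) / 2)
  m <- length(u)
  if (m < 2) stop("degenerate data: need at least two distinct values")
  mid <- (u[-m] + u[-1]) / 2
  sens <- (np - p_le[-m]) / np       # positives strictly above the midpoint
  spec <- q_le[-m] / nq
  j <- sens + spec - 1
  best <- which.max(j)               # first maximum = lowest threshold = highest sensitivity
  curve <- data.frame(cutoff = s * mid, sensitivity = sens, specificity = spec)
  list(auc = auc, cutoff = s * mid[best], youden_j = j[best],
       sensitivity = sens[best], specificity = spec[best],
       curve = curve[order(curve$cutoff), ])
}
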