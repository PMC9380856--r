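#' Normality gate for group comparisons
#'
#' Decides between the parametric and nonparametric comparison path: the
#' parametric path is taken only when every group passes the Shapiro-Wilk
#' test at `alpha` (default 0.05). The gate is applied per index across all
#' groups jointly, so one skewed group forces the rank test for every
#' pairwise comparison of that index. A constant-valued group cannot be
#' tested for normality and routes to the nonparametric path with a
#' warning.
#'
#' @param values_by_group Named list of numeric vectors, one per group
#'   (each n >= 3).
#' @param alpha Gate level.
#' @return List with `path` (`"parametric"`/`"nonparametric"`) and
#'   `shapiro_p` (named per-group p-values; `NA` for constant groups).
#' @export
normality_gate <- function(values_by_group, alpha = 0.05) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2)
  ns <- lengths(values_by_group)
  if (any(ns < 3)) stop("each group needs n >= 3 for the Shapiro-Wilk test")
  p <- vapply(values_by_group, function(x) {
    if (length(unique(x)) == 1L) NA_real_ else stats::shapiro.test(x)$p.value
  }, numeric(1))
  if (anyNA(p)) {
    warning("constant-valued group: routing to the nonparametric path")
    return(list(path = "nonparametric", shapiro_p = p))
  }
  list(path = if (all(p >= alpha)) "parametric" else "nonparametric", shapiro_p = p)
}

# LSD pairwise comparisons: plain t-tests on the pooled within-group
# variance from the one-way ANOVA, residual df, no multiplicity correction
# (that is the definition of Fisher's LSD).
lsd_pairwise <- function(values_by_group) {
  k <- length(values_by_group)
  ns <- lengths(values_by_group)
  means <- vapply(values_by_group, mean, numeric(1))
  N <- sum(ns)
  mse <- sum(vapply(values_by_group, function(x) sum((x - mean(x))^2), numeric(1))) / (N - k)
  pairs <- utils::combn(names(values_by_group), 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(mse * (1 / ns[[i]] + 1 / ns[[j]]))
    tt <- (means[[i]] - means[[j]]) / se
    data.frame(group1 = i, group2 = j,
               p_value = 2 * stats::pt(-abs(tt), df = N - k),
               stringsAsFactors = FALSE)
  }))
}

mwu_pairwise <- function(values_by_group) {
  pairs <- utils::combn(names(values_by_group), 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    p <- suppressWarnings(
      stats::wilcox.test(values_by_group[[pr[1]]], values_by_group[[pr[2]]])$p.value)
    data.frame(group1 = pr[1], group2 = pr[2], p_value = p, stringsAsFactors = FALSE)
  }))
}

#' Normality-gated pairwise group comparison of one index
#'
#' Parametric path: one-way ANOVA followed by LSD post hoc pairwise
#' comparisons (unadjusted t-tests on the pooled within-group variance).
#' Nonparametric path: pairwise two-sided Mann-Whitney U tests (exact when
#' sample sizes permit and there are no ties, otherwise the normal
#' approximation with tie correction).
#'
#' @param indices data.frame with a `group` column and the index column.
#' @param index_name Column to compare.
#' @param group_col Name of the grouping column.
#' @param alpha Normality-gate level.
#' @return Object of class `group_comparison`: list with `index_name`,
#'   `test_used` (`"ANOVA_LSD"` or `"MannWhitneyU"`), `shapiro_p`,
#'   `anova_p` (parametric path only), and `pairs` (data.frame `group1`,
#'   `group2`, `p_value`).
#' @export
compare_groups <- function(indices, index_name, group_col = "group", alpha = 0.05) {
  if (!index_name %in% names(indices)) stop("no such index column: ", index_name)
  vals <- split(indices[[index_name]], indices[[group_col]])
  if (length(vals) < 2) stop("need at least 2 groups")
  if (any(lengths(vals) < 3)) stop("each group needs n >= 3")
  gate <- normality_gate(vals, alpha)
  if (gate$path == "parametric") {
    grp <- factor(rep(names(vals), lengths(vals)))
    fit <- stats::aov(unlist(vals) ~ grp)
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    pairs <- lsd_pairwise(vals)
    test <- "ANOVA_LSD"
  } else {
    anova_p <- NA_real_
    pairs <- mwu_pairwise(vals)
    test <- "MannWhitneyU"
  }
  structure(list(index_name = index_name, test_used = test,
                 shapiro_p = gate$shapiro_p, anova_p = anova_p, pairs = pairs),
            class = "group_comparison")
}
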