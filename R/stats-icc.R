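#' Two-rater intraclass correlation, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement: the
#' standard model for inter-rater reliability of continuous measurements
#' when both raters score every subject and systematic rater offsets should
#' count against agreement. Computed from the mean squares of the
#' subjects x raters table:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with \eqn{MS_R} the between-subject, \eqn{MS_C} the between-rater and
#' \eqn{MS_E} the residual mean square.
#'
#' @param values An n x 2 numeric matrix or data.frame (subjects x raters),
#'   no missing values, n >= 3.
#' @return Object of class `icc_result`: list with `icc`, `band` (see
#'   [icc_agreement_level()]), `model`, `n`, and the mean squares.
#' @export
icc_two_rater <- function(values) {
  x <- as.matrix(values)
  if (ncol(x) != 2L) stop("expected exactly 2 raters (columns)")
  if (nrow(x) < 3L) stop("need n >= 3 subjects")
  if (anyNA(x)) stop("missing cells are not allowed")
  n <- nrow(x); k <- 2L
  grand <- mean(x)
  if (sum((x - grand)^2) == 0) stop("zero total variance: ICC undefined")
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - grand)^2) - k * sum((row_m - grand)^2) - n * sum((col_m - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(icc = icc, band = icc_agreement_level(icc),
                 model = "two-way random, absolute agreement, single rater (ICC(2,1))",
                 n = n, MSR = msr, MSC = msc, MSE = mse),
            class = "icc_result")
}

#' Agreement band for an ICC value
#'
#' Bands: below 0.3 slight agreement; 0.3 to 0.7 (inclusive at both ends)
#' moderate; above 0.7 good.
#'
#' @param icc Numeric ICC in (-1, 1].
#' @return `"slight"`, `"moderate"` or `"good"`.
#' @export
icc_agreement_level <- function(icc) {
  stopifnot(is.numeric(icc), length(icc) == 1L, icc > -1, icc <= 1)
  if (icc < 0.3) "slight" else if (icc <= 0.7) "moderate" else "good"
}
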