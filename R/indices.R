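#' Subject record: 2 raters x 2 sides of raw measurements
#'
#' Container for one subject's complete raw measurement set. Partial records
#' (a missing rater/side cell or CSF entry) are rejected, not imputed.
#'
#' @param measurements data.frame with exactly 4 rows and columns `rater`
#'   (1/2), `side` (`"left"`/`"right"`), `LL_mm`, `SL_mm`, `area_mm2`,
#'   `SIm`, `SIsd`.
#' @param csf data.frame with one row per rater: `rater`, `SIm_CSF`,
#'   `SIsd_CSF`.
#' @param subject_id,group_label Identifiers carried into the output.
#' @return Object of class `subject_record`.
#' @export
subject_record <- function(measurements, csf, subject_id = "S1", group_label = NA_character_) {
  need <- c("rater", "side", "LL_mm", "SL_mm", "area_mm2", "SIm", "SIsd")
  if (!all(need %in% names(measurements))) {
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste(measurements$rater, measurements$side)
  want <- c("1 left", "1 right", "2 left", "2 right")
  if (nrow(measurements) != 4L || !setequal(key, want)) {
    stop("incomplete record: need exactly the four (rater, side) cells for subject ", subject_id)
  }
  if (!all(1:2 %in% csf$rater) || nrow(csf) != 2L) {
    stop("incomplete record: need CSF measurements for both raters for subject ", subject_id)
  }
  structure(list(measurements = measurements[order(measurements$rater, measurements$side), ],
                 csf = csf[order(csf$rater), ],
                 subject_id = subject_id, group_label = group_label),
            class = "subject_record")
}

# split a long measurements table (one row per subject/rater/side, CSF
# columns repeated) into subject_record objects
as_subject_records <- function(measurements) {
  validate_measurements(measurements)
  ids <- unique(measurements$subject_id)
  lapply(ids, function(id) {
    m <- measurements[measurements$subject_id == id, ]
    csf <- unique(m[, c("rater", "SIm_CSF", "SIsd_CSF")])
    subject_record(m[, c("rater", "side", "LL_mm", "SL_mm", "area_mm2", "SIm", "SIsd")],
                   csf, subject_id = id, group_label = m$group[1])
  })
}

#' Validate a long-format measurements table
#'
#' Checks the column contract of the measurements CSV (one row per
#' subject/rater/side), completeness of every subject's four cells, and
#' within-rater consistency of the side-independent CSF columns.
#'
#' @param measurements data.frame as produced by [generate_cohort()] or
#'   [read_measurements()].
#' @return The table, invisibly, if valid; otherwise an error naming the
#'   offending subject or column.
#' @export
validate_measurements <- function(measurements) {
  need <- c("subject_id", "group", "rater", "side", "LL_mm", "SL_mm",
            "area_mm2", "SIm", "SIsd", "SIm_CSF", "SIsd_CSF")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) stop("measurements table missing columns: ", paste(miss, collapse = ", "))
  if (!all(measurements$side %in% c("left", "right"))) stop("side must be 'left' or 'right'")
  if (!all(measurements$rater %in% 1:2)) stop("rater must be 1 or 2")
  cnt <- table(measurements$subject_id)
  if (any(cnt != 4L)) {
    stop("incomplete record: subject(s) without exactly 4 rows: ",
         paste(names(cnt)[cnt != 4L], collapse = ", "))
  }
  for (id in unique(measurements$subject_id)) {
    m <- measurements[measurements$subject_id == id, ]
    for (r in 1:2) {
      mr <- m[m$rater == r, ]
      if (length(unique(mr$SIm_CSF)) != 1L || length(unique(mr$SIsd_CSF)) != 1L) {
        stop("CSF columns differ between sides for subject ", id, ", rater ", r,
             " (CSF is side-independent)")
      }
    }
  }
  invisible(measurements)
}

#' Per-side rater means
#'
#' For each side, averages the two raters' raw measurements field by field.
#'
#' @param record A [subject_record()].
#' @return data.frame with rows `left`, `right` and columns `LL_mm`,
#'   `SL_mm`, `area_mm2`, `SIm`, `SIsd`.
#' @export
rater_side_means <- function(record) {
  stopifnot(inherits(record, "subject_record"))
  m <- record$measurements
  out <- do.call(rbind, lapply(c("left", "right"), function(sd_) {
    ms <- m[m$side == sd_, c("LL_mm", "SL_mm", "area_mm2", "SIm", "SIsd")]
    as.data.frame(as.list(colMeans(ms)))
  }))
  rownames(out) <- c("left", "right")
  out
}

#' Uncorrected subject-level indices
#'
#' Each index is the mean over sides of the per-side rater means. The ratio
#' SLLr is aggregated ratio-first: per-side SL/LL from the rater-mean side
#' values, then averaged over sides (mean-of-ratios, not ratio-of-means).
#'
#' @param record A [subject_record()].
#' @return List with `SL`, `LL`, `SLLr`, `Area`, `SIm_LN`, `SIsd_LN`.
#' @export
uncorrected_indices <- function(record) {
  sm <- rater_side_means(record)
  list(SL = mean(sm$SL_mm), LL = mean(sm$LL_mm),
       SLLr = mean(sm$SL_mm / sm$LL_mm),
       Area = mean(sm$area_mm2), SIm_LN = mean(sm$SIm), SIsd_LN = mean(sm$SIsd))
}

#' Corrected short line (smaller side)
#'
#' The corrected short line takes the smaller of the two rater-mean side
#' values, reflecting that unilateral posterior narrowing is the
#' discriminating feature. An exact tie is broken toward the left side and
#' flagged.
#'
#' @param record A [subject_record()].
#' @return List with `cSL`, `csl_side`, `tie`.
#' @export
corrected_short_line <- function(record) {
  sm <- rater_side_means(record)
  tie <- sm["left", "SL_mm"] == sm["right", "SL_mm"]
  side <- if (sm["left", "SL_mm"] <= sm["right", "SL_mm"]) "left" else "right"
  list(cSL = sm[side, "SL_mm"], csl_side = side, tie = tie)
}

#' Corrected short/long ratio
#'
#' cSL divided by the rater-mean long line of the same (smaller-SL) side.
#'
#' @param record A [subject_record()].
#' @return cSLLr (dimensionless); warns if > 1.
#' @export
corrected_ratio <- function(record) {
  csl <- corrected_short_line(record)
  sm <- rater_side_means(record)
  ll <- sm[csl$csl_side, "LL_mm"]
  if (ll == 0) stop("zero LL on the corrected side")
  r <- csl$cSL / ll
  if (r > 1) warning("cSLLr > 1: short line exceeds long line on the corrected side")
  r
}

#' Corrected intensity SD (larger side)
#'
#' Takes the larger rater-mean side SIsd, reflecting that inhomogeneous
#' signal (iron deposition) is unilateral-dominant. Ties break toward left,
#' flagged.
#'
#' @param record A [subject_record()].
#' @return List with `cSIsd_LN`, `csisd_side`, `tie`.
#' @export
corrected_sisd <- function(record) {
  sm <- rater_side_means(record)
  tie <- sm["left", "SIsd"] == sm["right", "SIsd"]
  side <- if (sm["left", "SIsd"] >= sm["right", "SIsd"]) "left" else "right"
  list(cSIsd_LN = sm[side, "SIsd"], csisd_side = side, tie = tie)
}

#' Normalize lentiform intensity to the CSF reference
#'
#' Maps the ROI mean intensity onto a scale where the CSF mean equals 200:
#' `nSIm = 200 * SIm / SIm_CSF`. Invariant under global rescaling of the
#' image intensities.
#'
#' @param SIm Lentiform nucleus mean intensity (one side, one rater).
#' @param SIm_CSF That rater's CSF mean intensity (> 0).
#' @return Normalized intensity.
#' @export
normalize_intensity <- function(SIm, SIm_CSF) {
  if (any(SIm_CSF <= 0)) stop("SIm_CSF must be positive for normalization")
  200 * SIm / SIm_CSF
}

#' Compute all subject-level indices for one record
#'
#' Composes the per-side rater means, uncorrected indices, corrected-side
#' rules and CSF normalization into the full index vector. nSIm is
#' aggregated within-rater first (each rater's side-mean normalized
#' intensity against that rater's own CSF), then over raters.
#'
#' @param record A [subject_record()].
#' @return One-row data.frame with `subject_id`, `group`, the 12 indices
#'   (`cSL`, `SL`, `LL`, `cSLLr`, `SLLr`, `Area`, `SIm_LN`, `SIsd_LN`,
#'   `cSIsd_LN`, `SIm_CSF`, `SIsd_CSF`, `nSIm`), the corrected-side labels
#'   and tie flags.
#' @export
compute_subject_indices <- function(record) {
  un <- uncorrected_indices(record)
  csl <- corrected_short_line(record)
  csisd <- corrected_sisd(record)
  m <- record$measurements; csf <- record$csf
  nsim_r <- vapply(1:2, function(r) {
    mr <- m[m$rater == r, ]
    mean(normalize_intensity(mr$SIm, csf$SIm_CSF[csf$rater == r]))
  }, numeric(1))
  data.frame(subject_id = record$subject_id, group = record$group_label,
             cSL = csl$cSL, SL = un$SL, LL = un$LL,
             cSLLr = corrected_ratio(record), SLLr = un$SLLr,
             Area = un$Area, SIm_LN = un$SIm_LN, SIsd_LN = un$SIsd_LN,
             cSIsd_LN = csisd$cSIsd_LN,
             SIm_CSF = mean(csf$SIm_CSF), SIsd_CSF = mean(csf$SIsd_CSF),
             nSIm = mean(nsim_r),
             csl_side = csl$csl_side, csisd_side = csisd$csisd_side,
             csl_tie = csl$tie, csisd_tie = csisd$tie,
             stringsAsFactors = FALSE)
}

#' Compute subject indices for a whole cohort (vectorized)
#'
#' Batch equivalent of [compute_subject_indices()] over a long measurements
#' table; the two implementations are independent and agree exactly (this
#' is asserted in the test suite).
#'
#' @param measurements Long-format table, see [validate_measurements()].
#' @return data.frame, one row per subject, same columns as
#'   [compute_subject_indices()].
#' @export
compute_indices <- function(measurements) {
  validate_measurements(measurements)
  ids <- unique(measurements$subject_id)
  sid <- factor(measurements$subject_id, levels = ids)
  ord <- order(as.integer(sid), measurements$rater, measurements$side)
  m <- measurements[ord, ]
  n <- length(ids)
  # cell order per subject: r1 left, r1 right, r2 left, r2 right
  cell <- function(col) matrix(m[[col]], nrow = n, ncol = 4, byrow = TRUE)
  LL <- cell("LL_mm"); SL <- cell("SL_mm"); AR <- cell("area_mm2")
  IM <- cell("SIm"); ISD <- cell("SIsd"); CM <- cell("SIm_CSF"); CS <- cell("SIsd_CSF")
  lmean <- function(x) (x[, 1] + x[, 3]) / 2   # left cells
  rmean <- function(x) (x[, 2] + x[, 4]) / 2   # right cells
  SL_l <- lmean(SL); SL_r <- rmean(SL); LL_l <- lmean(LL); LL_r <- rmean(LL)
  ISD_l <- lmean(ISD); ISD_r <- rmean(ISD)
  csl_left <- SL_l <= SL_r
  csisd_left <- ISD_l >= ISD_r
  csf1 <- CM[, 1]; csf2 <- CM[, 4]  # rater 1 / rater 2 CSF means
  if (any(csf1 <= 0) || any(csf2 <= 0)) stop("SIm_CSF must be positive for normalization")
  nsim <- (200 * (IM[, 1] + IM[, 2]) / (2 * csf1) +
           200 * (IM[, 3] + IM[, 4]) / (2 * csf2)) / 2
  out <- data.frame(
    subject_id = ids,
    group = m$group[seq(1, nrow(m), by = 4)],
    cSL = ifelse(csl_left, SL_l, SL_r),
    SL = (SL_l + SL_r) / 2, LL = (LL_l + LL_r) / 2,
    cSLLr = ifelse(csl_left, SL_l / LL_l, SL_r / LL_r),
    SLLr = (SL_l / LL_l + SL_r / LL_r) / 2,
    Area = (lmean(AR) + rmean(AR)) / 2,
    SIm_LN = (lmean(IM) + rmean(IM)) / 2,
    SIsd_LN = (ISD_l + ISD_r) / 2,
    cSIsd_LN = ifelse(csisd_left, ISD_l, ISD_r),
    SIm_CSF = (csf1 + csf2) / 2, SIsd_CSF = (CS[, 1] + CS[, 4]) / 2,
    nSIm = nsim,
    csl_side = ifelse(csl_left, "left", "right"),
    csisd_side = ifelse(csisd_left, "left", "right"),
    csl_tie = SL_l == SL_r, csisd_tie = ISD_l == ISD_r,
    stringsAsFactors = FALSE)
  if (any(out$cSLLr > 1)) warning("cSLLr > 1 for subject(s): ",
                                  paste(out$subject_id[out$cSLLr > 1], collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Per-rater subject indices (for inter-rater agreement)
#'
#' Each rater's own side-mean index values per subject: the quantities
#' whose two-rater agreement the ICC quantifies. SLLr is the rater's mean
#' of per-side ratios; nSIm uses that rater's own CSF reference.
#'
#' @param measurements Long-format table, see [validate_measurements()].
#' @return data.frame with one row per (subject, rater) and columns `SL`,
#'   `LL`, `SLLr`, `Area`, `SIm`, `SIsd`, `nSIm`.
#' @export
rater_indices <- function(measurements) {
  validate_measurements(measurements)
  ids <- unique(measurements$subject_id)
  sid <- factor(measurements$subject_id, levels = ids)
  ord <- order(as.integer(sid), measurements$rater, measurements$side)
  m <- measurements[ord, ]
  g <- m[m$side == "left", ]  # one row per (subject, rater), ordered
  h <- m[m$side == "right", ]
  if (any(h$SIm_CSF <= 0) || any(g$SIm_CSF <= 0)) stop("SIm_CSF must be positive for normalization")
  data.frame(subject_id = g$subject_id, group = g$group, rater = g$rater,
             SL = (g$SL_mm + h$SL_mm) / 2, LL = (g$LL_mm + h$LL_mm) / 2,
             SLLr = (g$SL_mm / g$LL_mm + h$SL_mm / h$LL_mm) / 2,
             Area = (g$area_mm2 + h$area_mm2) / 2,
             SIm = (g$SIm + h$SIm) / 2, SIsd = (g$SIsd + h$SIsd) / 2,
             nSIm = (200 * g$SIm / g$SIm_CSF + 200 * h$SIm / h$SIm_CSF) / 2,
             stringsAsFactors = FALSE)
}
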