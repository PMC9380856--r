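#' Measurement frame for a 2D axial slice
#'
#' Fixes the geometric conventions shared by all measurement functions.
#' Images are numeric matrices with rows = y (increasing downward) and
#' columns = x (increasing rightward); pixel indices are 0-based in the
#' coordinate contract, so the centre of 0-based column `j` sits at
#' `(j + 0.5) * pixel_spacing` mm. All public inputs and outputs are in mm,
#' never pixels.
#'
#' @param pixel_spacing Isotropic pixel size in mm/px. Must be positive.
#' @param x_ref Anterior-posterior reference line position in mm (the
#'   vertical line whose intersection with the ROI defines the short line).
#'   May be `NA` when only spacing-dependent measures are needed.
#' @return An object of class `measurement_frame`.
#' @export
measurement_frame <- function(pixel_spacing, x_ref = NA_real_) {
  stopifnot(is.numeric(pixel_spacing), length(pixel_spacing) == 1L)
  if (!is.finite(pixel_spacing) || pixel_spacing <= 0) {
    stop("pixel_spacing must be a positive finite number (mm/px)")
  }
  structure(list(pixel_spacing = pixel_spacing, x_ref = as.numeric(x_ref)),
            class = "measurement_frame")
}

check_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1, TRUE, FALSE))) stop("non-binary mask: values other than 0/1 present")
  mask <- mask != 0
  if (!any(mask)) stop("empty mask: no pixels set")
  mask
}

#' Longest horizontal chord of a binary mask
#'
#' Scans every row that intersects the mask and returns the longest
#' endpoint-to-endpoint extent, the caliper convention a radiologist uses:
#' chord = (last column - first column + 1) * pixel_spacing. With
#' `convention = "runsum"` the in-mask run length is used instead; the two
#' agree on convex masks.
#'
#' @param mask Binary matrix (0/1 or logical).
#' @param frame A [measurement_frame()].
#' @param convention `"extent"` (default) or `"runsum"`.
#' @return A list with `LL` (mm) and `row` (0-based row index attaining it).
#' @export
longest_horizontal_chord <- function(mask, frame, convention = c("extent", "runsum")) {
  convention <- match.arg(convention)
  mask <- check_mask(mask)
  s <- frame$pixel_spacing
  rows <- which(rowSums(mask) > 0)
  chords <- vapply(rows, function(i) {
    cols <- which(mask[i, ])
    if (convention == "extent") (max(cols) - min(cols) + 1) * s else length(cols) * s
  }, numeric(1))
  k <- which.max(chords)
  list(LL = chords[k], row = rows[k] - 1L)
}

# 0-based column index of the pixel whose x-range contains x_ref
# (centres at (j + 0.5) * spacing; a boundary value maps to the pixel on
# its right, deterministically).
ref_column <- function(x_ref, pixel_spacing, ncol_img) {
  j <- floor(x_ref / pixel_spacing + 1e-9)
  if (j < 0 || j >= ncol_img) {
    stop(sprintf("reference line x_ref = %.3f mm falls outside the image", x_ref))
  }
  as.integer(j)
}

#' Vertical chord at the reference line (short line)
#'
#' Measures the short line: the vertical extent of the mask along the pixel
#' column containing `frame$x_ref`, endpoint-to-endpoint:
#' chord = (last row - first row + 1) * pixel_spacing.
#'
#' @inheritParams longest_horizontal_chord
#' @return Chord length in mm.
#' @export
vertical_chord_at <- function(mask, frame, convention = c("extent", "runsum")) {
  convention <- match.arg(convention)
  mask <- check_mask(mask)
  if (!is.finite(frame$x_ref)) stop("frame$x_ref must be set to measure a vertical chord")
  s <- frame$pixel_spacing
  j <- ref_column(frame$x_ref, s, ncol(mask)) + 1L  # to 1-based
  rows <- which(mask[, j])
  if (length(rows) == 0L) {
    stop(sprintf("no intersection: reference line x_ref = %.3f mm misses the mask", frame$x_ref))
  }
  if (convention == "extent") (max(rows) - min(rows) + 1) * s else length(rows) * s
}

#' ROI area
#'
#' @inheritParams longest_horizontal_chord
#' @return Area in mm^2 (pixel count times pixel_spacing squared).
#' @export
roi_area <- function(mask, frame) {
  mask <- check_mask(mask)
  sum(mask) * frame$pixel_spacing^2
}

#' Mean and standard deviation of signal intensity within an ROI
#'
#' The SD uses the sample (n - 1) denominator, matching the default of
#' clinical workstation ROI tools. A single-pixel mask yields SD 0 with a
#' warning.
#'
#' @param image Numeric matrix of signal intensities.
#' @param mask Binary matrix, same shape as `image`.
#' @return A list with `SIm` and `SIsd`.
#' @export
roi_intensity_stats <- function(image, mask) {
  if (!is.matrix(image)) stop("image must be a matrix")
  if (!all(dim(image) == dim(mask))) stop("shape mismatch between image and mask")
  mask <- check_mask(mask)
  px <- image[mask]
  if (length(px) == 1L) {
    warning("single-pixel mask: intensity SD reported as 0")
    return(list(SIm = px, SIsd = 0))
  }
  list(SIm = mean(px), SIsd = stats::sd(px))
}

#' Measure one lentiform nucleus side
#'
#' Bundles the raw per-side measurements taken on the standard axial slice:
#' longest horizontal line (LL), short line at the reference column (SL),
#' their ratio (SLLr = SL/LL), area, and in-mask intensity mean/SD.
#' SL > LL is geometrically suspicious for this ROI and raises a warning,
#' not an error.
#'
#' @inheritParams roi_intensity_stats
#' @param frame A [measurement_frame()] with `x_ref` set.
#' @param convention Chord convention, see [longest_horizontal_chord()].
#' @return An object of class `side_measurement`: list with `LL`, `SL`,
#'   `SLLr`, `area`, `SIm`, `SIsd` (mm / mm^2 / signal units).
#' @export
measure_side <- function(image, mask, frame, convention = c("extent", "runsum")) {
  convention <- match.arg(convention)
  ll <- longest_horizontal_chord(mask, frame, convention)
  sl <- vertical_chord_at(mask, frame, convention)
  if (sl > ll$LL) warning(sprintf("SL (%.2f mm) exceeds LL (%.2f mm)", sl, ll$LL))
  int <- roi_intensity_stats(image, mask)
  structure(list(LL = ll$LL, SL = sl, SLLr = sl / ll$LL,
                 area = roi_area(mask, frame),
                 SIm = int$SIm, SIsd = int$SIsd),
            class = "side_measurement")
}

#' Measure the cerebrospinal fluid reference ROI
#'
#' Intensity statistics of the CSF ROI (fourth ventricle), used to
#' normalize lentiform nucleus intensity.
#'
#' @inheritParams roi_intensity_stats
#' @return An object of class `csf_measurement`: list with `SIm_CSF`,
#'   `SIsd_CSF`.
#' @export
measure_csf <- function(image, csf_mask) {
  int <- roi_intensity_stats(image, csf_mask)
  if (int$SIm <= 0) warning("non-positive CSF mean intensity; normalization will fail")
  structure(list(SIm_CSF = int$SIm, SIsd_CSF = int$SIsd), class = "csf_measurement")
}
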