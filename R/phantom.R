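#' Elliptical ROI specification
#'
#' Axis-aligned ellipse standing in for a sketched ROI boundary. The ellipse
#' is chosen because its chords and area have closed forms, which makes every
#' downstream measurement testable against an exact oracle: the horizontal
#' diameter is `2a`, the vertical chord at horizontal offset `d` from the
#' centre is `2b*sqrt(1 - (d/a)^2)`, and the area is `pi*a*b`.
#'
#' @param center_x,center_y Centre in mm (slice frame).
#' @param semi_axis_a Horizontal semi-axis, mm (> 0).
#' @param semi_axis_b Vertical semi-axis, mm (> 0).
#' @param mean_intensity Added signal inside the ROI (on top of background).
#' @param sd_intensity Within-ROI Gaussian texture SD (>= 0).
#' @return Object of class `ellipse_roi_spec`.
#' @export
ellipse_roi_spec <- function(center_x, center_y, semi_axis_a, semi_axis_b,
                             mean_intensity = 0, sd_intensity = 0) {
  if (semi_axis_a <= 0 || semi_axis_b <= 0) stop("ellipse semi-axes must be positive")
  if (sd_intensity < 0) stop("sd_intensity must be >= 0")
  structure(list(center_x = center_x, center_y = center_y,
                 semi_axis_a = semi_axis_a, semi_axis_b = semi_axis_b,
                 mean_intensity = mean_intensity, sd_intensity = sd_intensity),
            class = "ellipse_roi_spec")
}

#' Phantom slice specification
#'
#' Describes one synthetic axial slice: two lentiform nucleus ellipses, a
#' CSF reference ellipse, global noise, and the per-side anterior-posterior
#' reference line positions at which the short line is measured.
#'
#' @param image_shape Integer vector `c(rows, cols)` in pixels.
#' @param pixel_spacing Isotropic spacing, mm/px.
#' @param left_ln,right_ln,csf_roi [ellipse_roi_spec()] objects.
#' @param background_intensity Background signal level.
#' @param noise_sd Global additive Gaussian noise SD.
#' @param x_ref_left,x_ref_right Reference line x positions (mm); each must
#'   intersect its side's ellipse.
#' @param seed Integer seed used when rendering.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape, pixel_spacing, left_ln, right_ln, csf_roi,
                         background_intensity = 0, noise_sd = 0,
                         x_ref_left, x_ref_right, seed = NULL) {
  stopifnot(length(image_shape) == 2L, pixel_spacing > 0)
  spec <- structure(list(image_shape = as.integer(image_shape),
                         pixel_spacing = pixel_spacing,
                         left_ln = left_ln, right_ln = right_ln, csf_roi = csf_roi,
                         background_intensity = background_intensity,
                         noise_sd = noise_sd,
                         x_ref_left = x_ref_left, x_ref_right = x_ref_right,
                         seed = seed),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  ext <- c(spec$image_shape[2], spec$image_shape[1]) * spec$pixel_spacing  # (x, y) mm
  inside <- function(e, name) {
    if (e$center_x - e$semi_axis_a < 0 || e$center_x + e$semi_axis_a > ext[1] ||
        e$center_y - e$semi_axis_b < 0 || e$center_y + e$semi_axis_b > ext[2]) {
      stop(sprintf("ROI '%s' extends outside the image bounds", name))
    }
  }
  inside(spec$left_ln, "left_ln"); inside(spec$right_ln, "right_ln")
  inside(spec$csf_roi, "csf_roi")
  hits <- function(xr, e, name) {
    if (abs(xr - e$center_x) >= e$semi_axis_a) {
      stop(sprintf("x_ref = %.3f mm does not intersect ROI '%s'", xr, name))
    }
  }
  hits(spec$x_ref_left, spec$left_ln, "left_ln")
  hits(spec$x_ref_right, spec$right_ln, "right_ln")
  invisible(spec)
}

# Rasterize: pixel included iff its centre satisfies the ellipse inequality.
rasterize_ellipse <- function(e, image_shape, pixel_spacing) {
  xc <- (seq_len(image_shape[2]) - 0.5) * pixel_spacing
  yc <- (seq_len(image_shape[1]) - 0.5) * pixel_spacing
  u <- (xc - e$center_x) / e$semi_axis_a
  v <- (yc - e$center_y) / e$semi_axis_b
  outer(v^2, u^2, `+`) <= 1
}

# Closed-form chords/area of an ellipse: the measurement oracle.
ellipse_truth <- function(e, x_ref) {
  d <- (x_ref - e$center_x) / e$semi_axis_a
  list(LL = 2 * e$semi_axis_a,
       SL = 2 * e$semi_axis_b * sqrt(max(0, 1 - d^2)),
       area = pi * e$semi_axis_a * e$semi_axis_b,
       mean_intensity = e$mean_intensity, sd_intensity = e$sd_intensity)
}

#' Render a phantom slice
#'
#' Produces an intensity image and binary ROI masks from a [phantom_spec()],
#' with closed-form ground truth for every quantity the morphometry module
#' measures. Intensity is `background + per-ROI mean + zero-mean Gaussian
#' texture (per ROI) + global Gaussian noise`.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `slice_bundle`: `image`, `left_mask`,
#'   `right_mask`, `csf_mask` (matrices), `pixel_spacing`, `x_ref_left`,
#'   `x_ref_right`, `seed`, and `ground_truth` (per-ROI closed forms:
#'   `LL`, `SL`, `area`, `mean_intensity`, `sd_intensity`).
#' @export
render_slice <- function(spec) {
  validate_phantom_spec(spec)
  render <- function() {
    sh <- spec$image_shape
    img <- matrix(spec$background_intensity, sh[1], sh[2])
    rois <- list(left = spec$left_ln, right = spec$right_ln, csf = spec$csf_roi)
    masks <- lapply(rois, rasterize_ellipse, image_shape = sh,
                    pixel_spacing = spec$pixel_spacing)
    for (nm in names(rois)) {
      m <- masks[[nm]]; e <- rois[[nm]]
      img[m] <- img[m] + e$mean_intensity
      if (e$sd_intensity > 0) img[m] <- img[m] + stats::rnorm(sum(m), 0, e$sd_intensity)
    }
    if (spec$noise_sd > 0) img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd), sh[1], sh[2])
    gt <- list(left = ellipse_truth(spec$left_ln, spec$x_ref_left),
               right = ellipse_truth(spec$right_ln, spec$x_ref_right),
               csf = ellipse_truth(spec$csf_roi, spec$csf_roi$center_x))
    structure(list(image = img,
                   left_mask = masks$left * 1L, right_mask = masks$right * 1L,
                   csf_mask = masks$csf * 1L,
                   pixel_spacing = spec$pixel_spacing,
                   x_ref_left = spec$x_ref_left, x_ref_right = spec$x_ref_right,
                   seed = spec$seed, ground_truth = gt),
              class = "slice_bundle")
  }
  if (is.null(spec$seed)) render() else withr::with_seed(spec$seed, render())
}

# 1-px binary morphology with a plus-shaped (4-neighbour) structuring
# element, used to emulate slightly tighter/looser rater ROI sketches.
shift_mat <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  r <- seq_len(nrow(m)); c <- seq_len(ncol(m))
  rs <- r - dr; cs <- c - dc
  ok_r <- rs >= 1 & rs <= nrow(m); ok_c <- cs >= 1 & cs <= ncol(m)
  out[r[ok_r], c[ok_c]] <- m[rs[ok_r], cs[ok_c]]
  out
}

binary_morph <- function(mask, op = c("none", "erode", "dilate")) {
  op <- match.arg(op)
  if (op == "none") return(mask)
  m <- mask != 0
  nb <- list(shift_mat(m, 1, 0), shift_mat(m, -1, 0),
             shift_mat(m, 0, 1), shift_mat(m, 0, -1))
  out <- if (op == "erode") m & nb[[1]] & nb[[2]] & nb[[3]] & nb[[4]]
         else m | nb[[1]] | nb[[2]] | nb[[3]] | nb[[4]]
  out * 1L
}
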