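#' Group-level index distribution parameters
#'
#' Parametric description of one diagnostic group's latent index
#' distributions, from which synthetic subjects are drawn. Each index is a
#' normal distribution truncated at zero by redraw. Bilateral asymmetry is
#' modelled as a fixed split: the two sides sit at `base +/- delta/2` with a
#' random sign, so the side mean reproduces the configured mean while the
#' smaller (larger) side is displaced by `delta/2`.
#'
#' @param group_label Group name, e.g. `"MSA-P"`, `"PD"`, `"CG"`.
#' @param n_subjects Number of subjects (>= 2).
#' @param means,sds Named numeric vectors with entries `SL`, `LL`, `area`,
#'   `SIm_LN`, `SIsd_LN`, `SIm_CSF`, `SIsd_CSF` (mm / mm^2 / signal units).
#' @param asymmetry_delta Expected left-right short-line difference, mm.
#' @param asymmetry_delta_sisd Expected left-right difference of the
#'   intensity SD, signal units.
#' @return Object of class `group_params`.
#' @export
group_params <- function(group_label, n_subjects, means, sds,
                         asymmetry_delta = 0, asymmetry_delta_sisd = 0) {
  needed <- c("SL", "LL", "area", "SIm_LN", "SIsd_LN", "SIm_CSF", "SIsd_CSF")
  means <- unlist(means); sds <- unlist(sds)
  if (!all(needed %in% names(means)) || !all(needed %in% names(sds))) {
    stop("means and sds must name all of: ", paste(needed, collapse = ", "))
  }
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (asymmetry_delta < 0 || asymmetry_delta_sisd < 0) stop("asymmetry deltas must be >= 0")
  structure(list(group_label = group_label, n_subjects = as.integer(n_subjects),
                 means = means[needed], sds = sds[needed],
                 asymmetry_delta = asymmetry_delta,
                 asymmetry_delta_sisd = asymmetry_delta_sisd),
            class = "group_params")
}

#' Two-rater measurement noise model
#'
#' Emulates independent re-measurement by two radiologists. In tabular mode
#' the SDs are additive Gaussian noise on each raw measurement; in image
#' mode `sd_length` perturbs the reference line position and the ROI masks
#' are independently eroded/dilated by at most 1 px per rater, so length,
#' area and intensity noise arise from the measurement process itself.
#'
#' @param sd_length Per-measurement length noise SD, mm.
#' @param sd_intensity Intensity noise SD, signal units.
#' @param sd_area Area noise SD, mm^2.
#' @return Object of class `rater_noise_model`.
#' @export
rater_noise_model <- function(sd_length = 0.5, sd_intensity = 25, sd_area = 8) {
  if (any(c(sd_length, sd_intensity, sd_area) < 0)) stop("all SDs must be >= 0")
  structure(list(sd_length = sd_length, sd_intensity = sd_intensity,
                 sd_area = sd_area),
            class = "rater_noise_model")
}

#' Default cohort configuration (three-group study design)
#'
#' Returns the shipped configuration with one [group_params()] block per
#' group (MSA-P, PD, CG; n = 19 each), encoding the published group-level
#' means and SDs of the morphometric indices. The asymmetry deltas are
#' calibrated as twice the gap between the side-mean and corrected
#' (smaller-side / larger-side) group means, so that corrected indices come
#' out at their published levels; this calibration is an assumption of the
#' generator, not a measured quantity.
#'
#' @param path Optional path to a JSON config; defaults to the shipped file.
#' @return List of `group_params`.
#' @export
default_cohort_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table3_defaults.json", package = "lentimorph")
  }
  read_cohort_config(path)
}

#' Read a cohort configuration from JSON
#'
#' @param path JSON file with an array of group blocks, each holding
#'   `group_label`, `n_subjects`, `means`, `sds`, and the asymmetry deltas.
#' @return List of [group_params()].
#' @export
read_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  groups <- raw$groups
  if (is.null(groups)) stop("cohort config: missing required key 'groups'")
  lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    group_params(g$group_label, g$n_subjects,
                 means = unlist(g$means), sds = unlist(g$sds),
                 asymmetry_delta = g$asymmetry_delta,
                 asymmetry_delta_sisd = g$asymmetry_delta_sisd)
  })
}

# positive draw by redraw (truncation at zero); `lower` shifts the bound so
# that e.g. base - delta/2 stays positive
draw_pos <- function(mean, sd, lower = 0, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    x <- stats::rnorm(1, mean, sd)
    if (x > lower) return(x)
  }
  stop("could not draw a positive value after ", max_tries, " tries")
}

# Default rendering geometry for image mode. One 64 x 64 mm slice at
# 0.5 mm/px; lentiform ellipses left/right of midline, CSF ellipse below.
# x_ref sits at 80% of the semi-axis toward the midline ("posterior" in the
# slice frame), where the short line of the real protocol is taken.
default_image_params <- function() {
  list(image_shape = c(128L, 128L), pixel_spacing = 0.5,
       center_left = c(20, 32), center_right = c(44, 32),
       csf_center = c(32, 48), csf_a = 4, csf_b = 2.5,
       background = 400, noise_sd = 5, x_ref_frac = 0.8)
}

draw_latents <- function(group, max_tries = 100L) {
  m <- group$means; s <- group$sds
  d_sl <- group$asymmetry_delta; d_sd <- group$asymmetry_delta_sisd
  for (i in seq_len(max_tries)) {
    base_sl <- draw_pos(m["SL"], s["SL"], lower = d_sl / 2)
    ll <- draw_pos(m["LL"], s["LL"])
    sgn <- sample(c(-1, 1), 1)
    sl <- c(left = base_sl + sgn * d_sl / 2, right = base_sl - sgn * d_sl / 2)
    if (max(sl) < ll) {
      base_sd <- draw_pos(m["SIsd_LN"], s["SIsd_LN"], lower = d_sd / 2)
      sgn2 <- sample(c(-1, 1), 1)
      sisd <- c(left = base_sd + sgn2 * d_sd / 2, right = base_sd - sgn2 * d_sd / 2)
      return(list(
        SL = sl, LL = ll, area = draw_pos(m["area"], s["area"]),
        SIm = draw_pos(m["SIm_LN"], s["SIm_LN"]), SIsd = sisd,
        SIm_CSF = draw_pos(m["SIm_CSF"], s["SIm_CSF"]),
        SIsd_CSF = draw_pos(m["SIsd_CSF"], s["SIsd_CSF"])))
    }
  }
  stop("infeasible latent geometry: SL >= LL after ", max_tries, " redraws")
}

# assemble the 4 (rater, side) measurement rows of one subject
subject_rows_df <- function(subject_id, group_label, LL, SL, area,
                                 SIm, SIsd, SIm_CSF, SIsd_CSF) {
  data.frame(subject_id = subject_id, group = group_label,
             rater = c(1L, 1L, 2L, 2L),
             side = c("left", "right", "left", "right"),
             LL_mm = LL, SL_mm = SL, area_mm2 = area,
             SIm = SIm, SIsd = SIsd, SIm_CSF = SIm_CSF, SIsd_CSF = SIsd_CSF,
             stringsAsFactors = FALSE)
}

generate_subject_tabular <- function(group, rater_noise, subject_id) {
  lat <- draw_latents(group)
  rn <- rater_noise
  LL <- SL <- ar <- im <- isd <- csf_m <- csf_s <- numeric(4)
  for (r in 1:2) {
    cm <- if (rn$sd_intensity > 0) draw_pos(lat$SIm_CSF, rn$sd_intensity) else lat$SIm_CSF
    cs <- max(0, lat$SIsd_CSF + if (rn$sd_intensity > 0) stats::rnorm(1, 0, rn$sd_intensity) else 0)
    for (k in 1:2) {
      sd_ <- c("left", "right")[k]
      i <- (r - 1L) * 2L + k
      LL[i] <- if (rn$sd_length > 0) draw_pos(lat$LL, rn$sd_length) else lat$LL
      SL[i] <- if (rn$sd_length > 0) draw_pos(lat$SL[sd_], rn$sd_length) else lat$SL[[sd_]]
      ar[i] <- if (rn$sd_area > 0) draw_pos(lat$area, rn$sd_area) else lat$area
      im[i] <- lat$SIm + if (rn$sd_intensity > 0) stats::rnorm(1, 0, rn$sd_intensity) else 0
      isd[i] <- max(0, lat$SIsd[sd_] + if (rn$sd_intensity > 0) stats::rnorm(1, 0, rn$sd_intensity) else 0)
      csf_m[i] <- cm; csf_s[i] <- cs
    }
  }
  out <- subject_rows_df(subject_id, group$group_label, LL, SL, ar, im, isd, csf_m, csf_s)
  attr(out, "latent") <- lat
  out
}

# Build a phantom matching the latent chords: a = LL/2 shared by both
# sides, per-side b chosen so the vertical chord at the reference offset
# equals the latent SL. Area in image mode therefore follows the ellipse
# geometry (pi*a*b), not the tabular area distribution.
phantom_from_latents <- function(lat, ip, seed = NULL) {
  a <- lat$LL / 2
  f <- ip$x_ref_frac
  b <- lat$SL / (2 * sqrt(1 - f^2))
  mk <- function(side, cx) {
    ellipse_roi_spec(cx[1], cx[2], a, b[[side]],
                     mean_intensity = lat$SIm - ip$background,
                     sd_intensity = lat$SIsd[[side]])
  }
  phantom_spec(
    image_shape = ip$image_shape, pixel_spacing = ip$pixel_spacing,
    left_ln = mk("left", ip$center_left), right_ln = mk("right", ip$center_right),
    csf_roi = ellipse_roi_spec(ip$csf_center[1], ip$csf_center[2], ip$csf_a, ip$csf_b,
                               mean_intensity = lat$SIm_CSF - ip$background,
                               sd_intensity = lat$SIsd_CSF),
    background_intensity = ip$background, noise_sd = ip$noise_sd,
    x_ref_left = ip$center_left[1] + f * a,
    x_ref_right = ip$center_right[1] - f * a,
    seed = seed)
}

generate_subject_image <- function(group, rater_noise, subject_id, image_params) {
  ip <- image_params
  # reject latent geometry the rendering frame cannot hold: the ellipse must
  # fit the slice, and the thinner side must still rasterize (semi-axis of
  # at least one pixel), so extreme low-tail short-line draws are redrawn
  for (i in seq_len(100L)) {
    lat <- draw_latents(group)
    a <- lat$LL / 2
    b <- lat$SL / (2 * sqrt(1 - ip$x_ref_frac^2))
    if (a < 11.5 && max(b) < 12 && min(b) >= ip$pixel_spacing) break
    if (i == 100L) stop("latent geometry does not fit the rendering frame")
  }
  spec <- phantom_from_latents(lat, ip)
  bundle <- render_slice(spec)
  LL <- SL <- ar <- im <- isd <- csf_m <- csf_s <- numeric(4)
  for (r in 1:2) {
    ops <- sample(c("none", "erode", "dilate"), 3, replace = TRUE)
    # a rater cannot sketch an empty ROI: if 1-px erosion would wipe out a
    # very thin mask, that rater effectively traces the rendered boundary
    perturb <- function(mask, op) {
      out <- binary_morph(mask, op)
      if (sum(out) == 0) mask else out
    }
    csf_mask <- perturb(bundle$csf_mask, ops[3])
    csf <- measure_csf(bundle$image, csf_mask)
    for (k in 1:2) {
      sd_ <- c("left", "right")[k]
      i <- (r - 1L) * 2L + k
      mask <- perturb(bundle[[paste0(sd_, "_mask")]], ops[k])
      e <- if (sd_ == "left") spec$left_ln else spec$right_ln
      xr0 <- bundle[[paste0("x_ref_", sd_)]]
      xr <- xr0 + stats::rnorm(1, 0, rater_noise$sd_length)
      # keep the perturbed reference line inside the ellipse; if the raster
      # column is empty near the rim (possible after erosion), pull the
      # line deterministically toward the centre until it hits the mask
      off <- max(-0.92, min(0.92, (xr - e$center_x) / e$semi_axis_a))
      sm <- NULL
      for (try in 1:25) {
        xr <- e$center_x + off * e$semi_axis_a
        sm <- tryCatch(
          measure_side(bundle$image, mask, measurement_frame(bundle$pixel_spacing, xr)),
          error = function(err) NULL)
        if (!is.null(sm)) break
        off <- off * 0.9
      }
      if (is.null(sm)) stop("could not measure side '", sd_, "': mask empty at every candidate column")
      LL[i] <- sm$LL; SL[i] <- sm$SL; ar[i] <- sm$area
      im[i] <- sm$SIm; isd[i] <- sm$SIsd
      csf_m[i] <- csf$SIm_CSF; csf_s[i] <- csf$SIsd_CSF
    }
  }
  out <- subject_rows_df(subject_id, group$group_label, LL, SL, ar, im, isd, csf_m, csf_s)
  attr(out, "latent") <- lat
  out
}

#' Generate one synthetic subject
#'
#' Draws a subject's latent per-side ground truth from the group
#' distributions, then produces the 2 raters x 2 sides measurement rows. In
#' `tabular` mode rater noise is added directly to the latent values; in
#' `image` mode a phantom slice is rendered to match the latent values and
#' each rater measures it through the morphometry functions, with an
#' independently perturbed reference line and a <= 1 px mask
#' erosion/dilation.
#'
#' @param group A [group_params()].
#' @param rater_noise A [rater_noise_model()].
#' @param mode `"tabular"` or `"image"`.
#' @param seed Integer seed (optional).
#' @param subject_id Identifier placed in the output rows.
#' @param image_params Rendering geometry (image mode only); see the
#'   package vignette. Defaults to a 64 x 64 mm slice at 0.5 mm/px.
#' @return A data.frame with 4 rows (rater x side) and columns
#'   `subject_id, group, rater, side, LL_mm, SL_mm, area_mm2, SIm, SIsd,
#'   SIm_CSF, SIsd_CSF`; the latent truth is attached as attribute
#'   `"latent"`.
#' @export
generate_subject <- function(group, rater_noise = rater_noise_model(),
                             mode = c("tabular", "image"), seed = NULL,
                             subject_id = "S1", image_params = default_image_params()) {
  mode <- match.arg(mode)
  gen <- function() {
    if (mode == "tabular") generate_subject_tabular(group, rater_noise, subject_id)
    else generate_subject_image(group, rater_noise, subject_id, image_params)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a synthetic cohort
#'
#' Concatenates subjects over all groups with stable per-subject seeds
#' (`seed + subject index`), so any individual subject can be regenerated
#' on its own.
#'
#' @param groups List of [group_params()] (>= 2, unique labels).
#' @inheritParams generate_subject
#' @return Long-format measurements data.frame, one row per
#'   (subject, rater, side).
#' @export
generate_cohort <- function(groups, rater_noise = rater_noise_model(),
                            mode = c("tabular", "image"), seed = NULL,
                            image_params = default_image_params()) {
  mode <- match.arg(mode)
  if (length(groups) < 2) stop("need at least 2 groups")
  labels <- vapply(groups, `[[`, "", "group_label")
  if (anyDuplicated(labels)) stop("duplicate group labels: ", paste(labels[duplicated(labels)], collapse = ", "))
  out <- list(); idx <- 0L
  for (g in groups) {
    for (i in seq_len(g$n_subjects)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", g$group_label, i)
      s <- if (is.null(seed)) NULL else (seed + idx) %% 2147483647L
      out[[idx]] <- generate_subject(g, rater_noise, mode, seed = s,
                                     subject_id = sid, image_params = image_params)
    }
  }
  # column-wise bind: far faster than rbind-ing thousands of small frames
  cols <- names(out[[1]])
  res <- as.data.frame(lapply(stats::setNames(cols, cols), function(cn) {
    unlist(lapply(out, `[[`, cn), use.names = FALSE)
  }), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
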