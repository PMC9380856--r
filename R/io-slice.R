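#' Write a slice bundle to disk
#'
#' Persists an intensity image plus the three ROI masks and the measurement
#' metadata. `"nifti"` stores each array as a 2D NIfTI file with the pixel
#' spacing in the header (and duplicated in a JSON sidecar); `"png"` stores
#' PNGs with the intensity scaling recorded in the sidecar, a
#' dependency-light alternative that is lossless for masks and metadata
#' (the intensity image is quantized to 8 bits; use NIfTI when exact
#' intensities matter).
#'
#' @param bundle A `slice_bundle` as returned by [render_slice()] or
#'   [read_slice_bundle()].
#' @param dir Output directory (created if needed).
#' @param format `"nifti"` or `"png"`.
#' @return `dir`, invisibly.
#' @export
write_slice_bundle <- function(bundle, dir, format = c("nifti", "png")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(pixel_spacing = bundle$pixel_spacing,
               x_ref_left = bundle$x_ref_left, x_ref_right = bundle$x_ref_right,
               format = format, seed = bundle$seed)
  arrays <- list(image = bundle$image, left_mask = bundle$left_mask,
                 right_mask = bundle$right_mask, csf_mask = bundle$csf_mask)
  if (format == "nifti") {
    for (nm in names(arrays)) {
      img <- RNifti::asNifti(arrays[[nm]] + 0)
      RNifti::pixdim(img) <- rep(bundle$pixel_spacing, 2)
      RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii")))
    }
  } else {
    rng <- range(bundle$image)
    meta$intensity_min <- rng[1]
    meta$intensity_max <- rng[2]
    scale <- if (diff(rng) > 0) diff(rng) else 1
    png::writePNG((bundle$image - rng[1]) / scale, file.path(dir, "image.png"))
    for (nm in c("left_mask", "right_mask", "csf_mask")) {
      png::writePNG(arrays[[nm]] + 0, file.path(dir, paste0(nm, ".png")))
    }
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a slice bundle from disk
#'
#' Reads a bundle written by [write_slice_bundle()] and validates it:
#' matching shapes, binary masks, complete metadata, and (for NIfTI)
#' agreement between header spacing and sidecar spacing. Each failure is a
#' distinct, named error.
#'
#' @param dir Directory containing the bundle.
#' @return A `slice_bundle` (without ground truth).
#' @export
read_slice_bundle <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("missing metadata: no meta.json in ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (key in c("pixel_spacing", "x_ref_left", "x_ref_right", "format")) {
    if (is.null(meta[[key]])) stop("missing metadata key: ", key)
  }
  nm4 <- c("image", "left_mask", "right_mask", "csf_mask")
  if (meta$format == "nifti") {
    arrays <- lapply(nm4, function(nm) {
      path <- file.path(dir, paste0(nm, ".nii"))
      if (!file.exists(path)) stop("missing array file: ", path)
      img <- RNifti::readNifti(path)
      hdr_spacing <- RNifti::pixdim(img)[1]
      if (abs(hdr_spacing - meta$pixel_spacing) > 1e-6) {
        stop(sprintf("conflicting pixel spacing for '%s': header %.6f mm vs sidecar %.6f mm",
                     nm, hdr_spacing, meta$pixel_spacing))
      }
      matrix(as.vector(img), nrow = dim(img)[1])
    })
  } else if (meta$format == "png") {
    arrays <- lapply(nm4, function(nm) {
      path <- file.path(dir, paste0(nm, ".png"))
      if (!file.exists(path)) stop("missing array file: ", path)
      png::readPNG(path)
    })
    arrays[[1]] <- arrays[[1]] * (meta$intensity_max - meta$intensity_min) + meta$intensity_min
  } else stop("unknown bundle format: ", meta$format)
  names(arrays) <- nm4
  shp <- dim(arrays$image)
  for (nm in nm4[-1]) {
    if (!all(dim(arrays[[nm]]) == shp)) stop("shape mismatch: ", nm, " differs from image")
    if (!all(arrays[[nm]] %in% c(0, 1))) stop("non-binary mask: ", nm)
    arrays[[nm]] <- matrix(as.integer(arrays[[nm]] != 0), nrow = shp[1])
  }
  structure(c(arrays,
              list(pixel_spacing = meta$pixel_spacing,
                   x_ref_left = meta$x_ref_left, x_ref_right = meta$x_ref_right,
                   seed = meta$seed, ground_truth = NULL)),
            class = "slice_bundle")
}
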