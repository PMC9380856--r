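test_that("chords of rasterized ellipses match the closed forms within raster tolerance", {
  s <- 0.5
  fr <- measurement_frame(s, x_ref = 20)
  b <- render_test_ellipse(a = 7.5, b = 3, x_ref_off = 0, spacing = s)
  expect_lt(abs(longest_horizontal_chord(b$left_mask, fr)$LL - 15), 2 * s)
  expect_lt(abs(vertical_chord_at(b$left_mask, fr) - 6), 2 * s)

  fr_off <- measurement_frame(s, x_ref = 26)
  b2 <- render_test_ellipse(a = 7.5, b = 3, x_ref_off = 6, spacing = s)
  expect_lt(abs(vertical_chord_at(b2$left_mask, fr_off) - 3.6), 2 * s)
})

test_that("degenerate masks: single pixel, empty mask, missing reference column", {
  fr <- measurement_frame(1.0, x_ref = 2.5)
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  expect_equal(longest_horizontal_chord(m, fr)$LL, 1.0)
  expect_equal(vertical_chord_at(m, fr), 1.0)
  expect_equal(roi_area(m, fr), 1.0)

  expect_error(longest_horizontal_chord(matrix(0L, 5, 5), fr), "empty mask")
  fr_miss <- measurement_frame(1.0, x_ref = 0.5)
  expect_error(vertical_chord_at(m, fr_miss), "no intersection.*0\\.5")
  fr_out <- measurement_frame(1.0, x_ref = 99)
  expect_error(vertical_chord_at(m, fr_out), "outside the image")
  m2 <- m; m2[2, 2] <- 2L
  expect_error(roi_area(m2, fr), "non-binary")
})

test_that("longest chord equals an independent brute-force row scan on random blobs", {
  set.seed(77)
  fr <- measurement_frame(0.5)
  for (i in 1:50) {
    m <- random_blob_mask(40, 40)
    expect_equal(longest_horizontal_chord(m, fr)$LL, brute_longest_chord(m, 0.5))
  }
})

test_that("area is the pixel count times spacing squared, ellipse area within 3%", {
  fr <- measurement_frame(0.5)
  m <- matrix(0L, 6, 6); m[2, 2:6] <- 1L; m[3, 1:5] <- 1L  # 10 pixels
  expect_equal(roi_area(m, fr), 2.5)

  b <- render_test_ellipse(a = 7.5, b = 3)
  expect_lt(abs(roi_area(b$left_mask, fr) - pi * 7.5 * 3) / (pi * 7.5 * 3), 0.03)

  set.seed(12)
  for (i in 1:20) {
    m <- random_blob_mask(30, 30)
    expect_equal(roi_area(m, fr), sum(m != 0) * 0.25)
  }
})

test_that("intensity statistics use the sample SD and match a two-pass oracle", {
  img <- matrix(500, 8, 8)
  m <- matrix(0L, 8, 8); m[3:5, 3:5] <- 1L
  expect_equal(roi_intensity_stats(img, m), list(SIm = 500, SIsd = 0))

  img2 <- matrix(0, 4, 4); img2[1, 1] <- 400; img2[1, 2] <- 600
  m2 <- matrix(0L, 4, 4); m2[1, 1:2] <- 1L
  st <- roi_intensity_stats(img2, m2)
  expect_equal(st$SIm, 500)
  expect_equal(st$SIsd, 200 / sqrt(2))  # |600-400|/sqrt(2)

  set.seed(41)
  for (i in 1:10) {
    img3 <- matrix(rnorm(900, 500, 80), 30, 30)
    m3 <- random_blob_mask(30, 30)
    got <- roi_intensity_stats(img3, m3)
    ora <- brute_intensity(img3, m3)
    expect_equal(got$SIm, ora$SIm)
    expect_equal(got$SIsd, ora$SIsd)
  }

  expect_error(roi_intensity_stats(matrix(0, 2, 2), matrix(1L, 3, 3)), "shape mismatch")
  one <- matrix(0L, 3, 3); one[2, 2] <- 1L
  expect_warning(st1 <- roi_intensity_stats(matrix(7, 3, 3), one), "single-pixel")
  expect_equal(st1$SIsd, 0)
})

test_that("chords scale linearly and area quadratically with pixel spacing", {
  set.seed(9)
  m <- random_blob_mask(30, 30)
  for (s in c(0.25, 0.5, 1, 2)) {
    fr <- measurement_frame(s)
    expect_equal(longest_horizontal_chord(m, fr)$LL,
                 s * longest_horizontal_chord(m, measurement_frame(1))$LL)
    expect_equal(roi_area(m, fr), s^2 * roi_area(m, measurement_frame(1)))
  }
})

test_that("extent chords are invariant to interior holes; runsum agrees on convex masks", {
  b <- render_test_ellipse(a = 7, b = 4)
  m <- b$left_mask
  fr <- measurement_frame(0.5, x_ref = 20)
  holey <- m
  holey[38:42, 38:42] <- 0L  # knock out the centre (rows/cols around (20,20)mm)
  expect_equal(longest_horizontal_chord(holey, fr)$LL, longest_horizontal_chord(m, fr)$LL)
  expect_equal(vertical_chord_at(holey, fr), vertical_chord_at(m, fr))

  # on the convex (un-holed) mask, extent and run-sum conventions coincide
  expect_equal(longest_horizontal_chord(m, fr, convention = "runsum")$LL,
               longest_horizontal_chord(m, fr)$LL)
  expect_equal(vertical_chord_at(m, fr, convention = "runsum"),
               vertical_chord_at(m, fr))
  # but on the holed mask, run-sum shrinks while extent does not
  expect_lt(vertical_chord_at(holey, fr, convention = "runsum"),
            vertical_chord_at(holey, fr))
})

test_that("measure_side bundles all fields and matches phantom ground truth", {
  b <- render_test_ellipse(a = 7.5, b = 3, x_ref_off = 2)
  fr <- measurement_frame(0.5, x_ref = 22)
  sm <- measure_side(b$image, b$left_mask, fr)
  gt <- b$ground_truth$left
  expect_s3_class(sm, "side_measurement")
  expect_lt(abs(sm$LL - gt$LL), 1.0)
  expect_lt(abs(sm$SL - gt$SL), 1.0)
  expect_lt(abs(sm$area - gt$area) / gt$area, 0.03)
  expect_equal(sm$SIm, 100)   # noiseless: background 0 + mean 100
  expect_equal(sm$SIsd, 0)
  expect_equal(sm$SLLr, sm$SL / sm$LL)

  # circle with central reference: SLLr = 1 within raster tolerance
  bc <- render_test_ellipse(a = 5, b = 5, x_ref_off = 0)
  smc <- measure_side(bc$image, bc$left_mask, measurement_frame(0.5, 20))
  expect_lt(abs(smc$SLLr - 1), 0.1)

  # CSF measurement mirrors roi_intensity_stats
  csf <- measure_csf(b$image, b$csf_mask)
  expect_s3_class(csf, "csf_measurement")
  expect_equal(csf$SIm_CSF, roi_intensity_stats(b$image, b$csf_mask)$SIm)
})
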