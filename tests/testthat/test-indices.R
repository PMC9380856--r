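test_that("rater-side means and the corrected-side rules follow their definitions", {
  # rater SLs 4.2 / 3.8 on the left -> left mean 4.0; right 5.4 / 5.0 -> 5.2
  rec <- make_record(ll = c(14, 15, 14.4, 15.2), sl = c(4.2, 5.4, 3.8, 5.0),
                     area = c(150, 160, 148, 158), sim = c(700, 650, 720, 640),
                     sisd = c(160, 120, 170, 110),
                     csf_m = c(1050, 1070), csf_s = c(40, 45))
  sm <- rater_side_means(rec)
  expect_equal(sm["left", "SL_mm"], 4.0)
  expect_equal(sm["right", "SL_mm"], 5.2)

  csl <- corrected_short_line(rec)
  expect_equal(csl$cSL, 4.0)
  expect_equal(csl$csl_side, "left")
  expect_false(csl$tie)

  cs <- corrected_sisd(rec)
  expect_equal(cs$cSIsd_LN, 165)       # left mean 165 > right mean 115
  expect_equal(cs$csisd_side, "left")

  expect_equal(corrected_ratio(rec), 4.0 / 14.2)  # same-side LL mean

  # exact tie breaks toward left, flagged
  tied <- make_record(ll = rep(14, 4), sl = rep(4, 4), area = rep(150, 4),
                      sim = rep(700, 4), sisd = rep(120, 4),
                      csf_m = c(1000, 1000), csf_s = c(40, 40))
  expect_true(corrected_short_line(tied)$tie)
  expect_equal(corrected_short_line(tied)$csl_side, "left")
  expect_true(corrected_sisd(tied)$tie)
})

test_that("SLLr is aggregated ratio-first (mean of per-side ratios)", {
  # sides with SL/LL = 4/10 and 6/20: mean of ratios 0.35, not 10/30
  rec <- make_record(ll = c(10, 20, 10, 20), sl = c(4, 6, 4, 6),
                     area = rep(100, 4), sim = rep(500, 4), sisd = rep(50, 4),
                     csf_m = c(1000, 1000), csf_s = c(40, 40))
  un <- uncorrected_indices(rec)
  expect_equal(un$SLLr, 0.35)
  expect_false(isTRUE(all.equal(un$SLLr, un$SL / un$LL)))  # differs from ratio-of-means
})

test_that("intensity normalization maps the CSF mean to 200 and rejects bad input", {
  expect_equal(normalize_intensity(1066.31, 1066.31), 200)
  expect_equal(normalize_intensity(698.13, 1066.31), 200 * 698.13 / 1066.31)
  expect_error(normalize_intensity(500, 0), "positive")
  expect_error(normalize_intensity(500, -10), "positive")
})

test_that("compute_subject_indices matches an independent spreadsheet-style oracle", {
  rec <- make_record(ll = c(14, 15, 14.4, 15.2), sl = c(4.2, 5.4, 3.8, 5.0),
                     area = c(150, 160, 148, 158), sim = c(700, 650, 720, 640),
                     sisd = c(160, 120, 170, 110),
                     csf_m = c(1050, 1070), csf_s = c(40, 45))
  out <- compute_subject_indices(rec)
  # hand arithmetic, every field
  expect_equal(out$SL, (4.0 + 5.2) / 2)
  expect_equal(out$LL, (14.2 + 15.1) / 2)
  expect_equal(out$SLLr, (4.0 / 14.2 + 5.2 / 15.1) / 2)
  expect_equal(out$Area, (149 + 159) / 2)
  expect_equal(out$SIm_LN, (710 + 645) / 2)
  expect_equal(out$SIsd_LN, (165 + 115) / 2)
  expect_equal(out$cSL, 4.0)
  expect_equal(out$cSLLr, 4.0 / 14.2)
  expect_equal(out$cSIsd_LN, 165)
  expect_equal(out$SIm_CSF, 1060)
  expect_equal(out$SIsd_CSF, 42.5)
  expect_equal(out$nSIm,
               (200 * (700 / 1050 + 650 / 1050) / 2 +
                200 * (720 / 1070 + 640 / 1070) / 2) / 2)
  expect_equal(out$csl_side, "left")
  expect_equal(out$csisd_side, "left")
})

test_that("fully symmetric records collapse corrected onto uncorrected indices", {
  rec <- make_record(ll = rep(14, 4), sl = rep(4.2, 4), area = rep(150, 4),
                     sim = rep(700, 4), sisd = rep(120, 4),
                     csf_m = c(1000, 1000), csf_s = c(40, 40))
  out <- compute_subject_indices(rec)
  expect_equal(out$cSL, out$SL)
  expect_equal(out$cSLLr, out$SLLr)
  expect_equal(out$cSIsd_LN, out$SIsd_LN)
})

test_that("vectorized cohort indices agree exactly with the per-record path", {
  cfg <- default_cohort_config()
  coh <- generate_cohort(cfg, mode = "tabular", seed = 31)
  batch <- compute_indices(coh)
  recs <- lentimorph:::as_subject_records(coh)
  single <- do.call(rbind, lapply(recs, compute_subject_indices))
  rownames(single) <- NULL
  expect_equal(batch, single[, names(batch)])
  expect_false(anyNA(batch[, !(names(batch) %in% c("csl_tie", "csisd_tie"))]))
})

test_that("corrected-index orderings hold for every generated subject", {
  cfg <- default_cohort_config()
  for (s in c(1, 2, 3)) {
    idx <- compute_indices(generate_cohort(cfg, mode = "tabular", seed = s))
    expect_true(all(idx$cSL <= idx$SL + 1e-12))
    expect_true(all(idx$cSIsd_LN >= idx$SIsd_LN - 1e-12))
  }
})

test_that("indices are invariant to rater relabelling and side relabelling", {
  cfg <- default_cohort_config()
  coh <- generate_cohort(cfg[1:2], mode = "tabular", seed = 8)
  base <- compute_indices(coh)

  sw_r <- coh; sw_r$rater <- 3L - sw_r$rater
  expect_equal(compute_indices(sw_r)[, 1:14], base[, 1:14])

  sw_s <- coh; sw_s$side <- ifelse(sw_s$side == "left", "right", "left")
  swapped <- compute_indices(sw_s)
  expect_equal(swapped[, 1:14], base[, 1:14])   # values unchanged
  noties <- !base$csl_tie
  expect_true(all(swapped$csl_side[noties] != base$csl_side[noties]))  # label flips
})

test_that("nSIm is invariant under global multiplicative intensity rescaling", {
  cfg <- default_cohort_config()
  coh <- generate_cohort(cfg[1:2], mode = "tabular", seed = 13)
  base <- compute_indices(coh)
  scaled <- coh
  for (cn in c("SIm", "SIsd", "SIm_CSF", "SIsd_CSF")) scaled[[cn]] <- scaled[[cn]] * 3.7
  expect_equal(compute_indices(scaled)$nSIm, base$nSIm)
})

test_that("partial records are rejected, not patched", {
  cfg <- default_cohort_config()
  coh <- generate_cohort(cfg[1:2], mode = "tabular", seed = 2)
  expect_error(compute_indices(coh[-1, ]), "incomplete record")
  bad <- coh
  bad$SIm_CSF[1] <- bad$SIm_CSF[1] + 5  # CSF must be side-independent
  expect_error(compute_indices(bad), "CSF columns differ")
  expect_error(subject_record(data.frame(rater = 1, side = "left", LL_mm = 1,
                                         SL_mm = 1, area_mm2 = 1, SIm = 1, SIsd = 1),
                              data.frame(rater = 1:2, SIm_CSF = 1, SIsd_CSF = 1)),
               "incomplete record")
})
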