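# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: naive loops, closed forms, enumeration.

# naive row-by-row scan for the longest horizontal chord (extent convention)
brute_longest_chord <- function(mask, spacing) {
  best <- -Inf
  for (i in seq_len(nrow(mask))) {
    cols <- which(mask[i, ] != 0)
    if (length(cols) > 0) {
      v <- (max(cols) - min(cols) + 1) * spacing
      if (v > best) best <- v
    }
  }
  best
}

# two-pass mean / sample SD
brute_intensity <- function(image, mask) {
  px <- image[mask != 0]
  m <- sum(px) / length(px)
  list(SIm = m, SIsd = sqrt(sum((px - m)^2) / (length(px) - 1)))
}

# mean of N(mu, sigma) truncated below at `lower` (redraw truncation)
trunc_normal_mean <- function(mu, sigma, lower = 0) {
  a <- (lower - mu) / sigma
  mu + sigma * dnorm(a) / (1 - pnorm(a))
}

# random mask: union of a few rectangles and discs on an nr x nc grid
random_blob_mask <- function(nr, nc) {
  m <- matrix(0L, nr, nc)
  for (b in seq_len(sample(1:3, 1))) {
    if (runif(1) < 0.5) {
      r0 <- sample(nr, 1); c0 <- sample(nc, 1)
      r1 <- min(nr, r0 + sample(1:8, 1)); c1 <- min(nc, c0 + sample(1:8, 1))
      m[r0:r1, c0:c1] <- 1L
    } else {
      cr <- sample(nr, 1); cc <- sample(nc, 1); rad <- sample(2:6, 1)
      for (i in seq_len(nr)) for (j in seq_len(nc)) {
        if ((i - cr)^2 + (j - cc)^2 <= rad^2) m[i, j] <- 1L
      }
    }
  }
  if (sum(m) == 0) m[sample(nr, 1), sample(nc, 1)] <- 1L
  m
}

# a complete 2x2 subject record from explicit numbers
make_record <- function(ll, sl, area, sim, sisd, csf_m, csf_s,
                        subject_id = "S1", group = "G") {
  subject_record(
    data.frame(rater = c(1L, 1L, 2L, 2L),
               side = c("left", "right", "left", "right"),
               LL_mm = ll, SL_mm = sl, area_mm2 = area, SIm = sim, SIsd = sisd),
    data.frame(rater = 1:2, SIm_CSF = csf_m, SIsd_CSF = csf_s),
    subject_id = subject_id, group_label = group)
}

# simple noiseless rendered ellipse for morphometry tests
render_test_ellipse <- function(a, b, x_ref_off = 0, spacing = 0.5,
                                center = c(20, 20), shape = c(80, 80)) {
  e <- ellipse_roi_spec(center[1], center[2], a, b,
                        mean_intensity = 100, sd_intensity = 0)
  dummy1 <- ellipse_roi_spec(32, 32, 1.5, 1.5, mean_intensity = 50)
  dummy2 <- ellipse_roi_spec(5, 5, 1.5, 1.5, mean_intensity = 600)
  sp <- phantom_spec(shape, spacing, e, dummy1, dummy2,
                     background_intensity = 0, noise_sd = 0,
                     x_ref_left = center[1] + x_ref_off, x_ref_right = 32, seed = 1)
  render_slice(sp)
}
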