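---
title: "Chord morphometry of the lentiform nucleus: model, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chord morphometry of the lentiform nucleus: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lentimorph)
```

## The measurement protocol

On susceptibility-weighted MRI, the parkinsonian subtype of multiple system
atrophy (MSA-P) is characterized by narrowing and inhomogeneous signal of the
posterior lentiform nucleus (LN), where iron deposition and neuronal loss
concentrate. The protocol implemented here quantifies that with two caliper
chords per side on a standard axial slice:

* **LL** — the longest horizontal line through the LN region of interest;
* **SL** — the vertical ("short") line where a fixed anterior–posterior
  reference line crosses the ROI;
* **SLLr** = SL/LL, a size-free shape index;
* **area**, and the in-ROI intensity mean **SIm_LN** and SD **SIsd_LN**;
* **SIm_CSF / SIsd_CSF** from a cerebrospinal-fluid ROI (fourth ventricle),
  used to normalize intensity: **nSIm** = 200 × SIm_LN / SIm_CSF, so CSF maps
  to 200 regardless of scanner scaling.

Both sides are measured by two raters. Subject-level indices are aggregated
side-mean-first within rater, then across raters. Because the degeneration is
often asymmetric, *corrected* indices take the informative side instead of
the mean: **cSL** is the smaller rater-mean side SL, **cSLLr** divides cSL by
the *same side's* LL, and **cSIsd_LN** is the larger rater-mean side SIsd.
By construction cSL ≤ SL and cSIsd_LN ≥ SIsd_LN for every subject; the test
suite asserts both orderings cohort-wide.

Two aggregation details are deliberate and documented because the
alternatives give different numbers:

* **SLLr is a mean of per-side ratios** (each side's SL/LL first, then
  averaged), not a ratio of means. For SL/LL of 4/10 and 6/20 this yields
  0.35, not 10/30 ≈ 0.33.
* **Corrected sides are chosen on rater-mean values**, not per rater. Exact
  ties (probability zero on continuous data) break deterministically toward
  the left side and are flagged in the output.

## Geometric conventions

Images are matrices (rows = y downward, columns = x rightward) with isotropic
`pixel_spacing` in mm/px; all public quantities are in mm, never pixels.
Chords use the **endpoint-to-endpoint extent** convention,
`(last − first + 1) × spacing`, matching how a radiologist sets calipers; a
`"runsum"` switch (sum of in-mask run lengths) is available for sensitivity
analysis. The two agree exactly on convex masks, and the extent convention is
invariant to interior signal dropout (holes). The reference coordinate
`x_ref` maps to the pixel column whose x-range contains it; sub-pixel
interpolation would be false precision at 0.5–0.8 mm spacing. Intensity SDs
use the sample (n − 1) denominator, matching clinical workstation ROI tools.

## The phantom generator

Because the underlying patient measurements are not public, the package
ships a synthetic stand-in with exact ground truth. The LN stand-in is an
axis-aligned ellipse: its horizontal diameter (2a), vertical chord at offset
d (2b·√(1 − (d/a)²)) and area (π·a·b) are closed forms, so every measurement
function can be tested against an oracle. Rendering rasterizes by pixel
centre and adds `background + per-ROI mean + per-ROI Gaussian texture +
global Gaussian noise`. Noise is Gaussian rather than Rician: at the signal
levels involved the SNR is high and the two are indistinguishable for these
statistics. The CSF ROI is rendered on the same slice; in the clinical
protocol it sits on a different plane, but nothing measured here depends on
that.

At the default 0.5 mm/px, rasterized chords agree with the closed forms
within 2 px and areas within 3% (asserted on randomized ellipses with
non-grid-aligned centres; a centre pinned exactly to a pixel-grid corner is
an adversarial alignment that can push area errors slightly past 3%).

### Cohort simulation and its calibration

`default_cohort_config()` encodes the three study groups (MSA-P, PD,
control; n = 19 each) with the published group-level means and SDs for SL,
LL, area, SIm_LN, SIsd_LN, SIm_CSF and SIsd_CSF. Per subject, a latent base
value is drawn per index (normal, truncated at zero by redraw — negative
lengths and intensities are not physical); left/right short lines sit at
`base ± delta/2` with random sign, and similarly for the intensity SD.

The asymmetry deltas are **calibration assumptions, not published
measurements**: the study reports no left–right difference magnitude, so the
deltas are set to twice the gap between the published side-mean and
corrected-index group means (SL: 1.70/1.06/0.96 mm; SIsd: 54.2/18.1/21.8
signal units). With that choice the expected smaller-side mean lands at the
published corrected-index level (e.g. MSA-P cSL ≈ 4.22 mm) up to the small
positive shift the zero-truncation itself introduces (≈ +0.06 mm for MSA-P
cSL; the large-sample generator test quantifies this against a
truncated-normal oracle rather than pretending it away).

Two measurement modes emulate the two raters:

* **tabular** — additive Gaussian rater noise on each raw value
  (defaults: 0.5 mm on lengths, 8 mm² on area, 25 signal units on
  intensities — plausible re-measurement variability for manual PACS ROIs);
* **image** — a phantom slice is rendered to match the latent chords
  (ellipse a = LL/2, per-side b chosen so the chord at the reference line
  equals the latent SL, reference line at 80% of the semi-axis to mimic the
  posterior measurement site) and each rater measures it through the
  morphometry functions with an independently jittered reference line and a
  ≤ 1 px mask erosion/dilation. A perturbation that would empty a very thin
  mask falls back to the rendered boundary (a rater cannot sketch an empty
  ROI). In image mode the measured area follows the ellipse geometry
  (π·a·b), not the tabular area distribution — an ellipse cannot match both
  the chords and the published area simultaneously, and the chords are the
  discriminating quantities.

What passing tests on this generator do **not** show: robustness to real
anatomy (non-elliptical, sheared, partial-volume boundaries), to slice
selection variability (the standard plane is an input here, chosen manually
in practice), or to rater disagreement structure beyond additive
noise/1-px morphology. The published inter-rater ICC table reflects those
real-data effects and is deliberately out of reach of this generator.

## Statistics

* **Group comparisons** are normality-gated per index across all groups
  jointly: if every group passes Shapiro–Wilk at α = 0.05, one-way ANOVA
  with Fisher's LSD post hoc (pairwise t-tests on the pooled within-group
  variance, residual df, *no* multiplicity correction — that is what LSD
  means); otherwise pairwise two-sided Mann–Whitney U (exact when sample
  sizes permit and no ties; normal approximation with tie correction
  otherwise). A constant-valued group routes to the rank path with a
  warning rather than erroring.
* **ICC** uses ICC(2,1) — two-way random effects, absolute agreement,
  single measurement — computed from mean squares. The clinical source
  never names a variant; ICC(2,1) is the standard choice when systematic
  rater offsets should count against agreement, and the model descriptor is
  carried in the output so alternatives can be compared. It is computed on
  each rater's side-mean values per subject. Agreement bands: < 0.3 slight,
  0.3–0.7 (inclusive) moderate, > 0.7 good.
* **ROC** curves are empirical. Orientation is chosen so the positive
  group's mean is on the positive side (recorded in the output; flipped
  with a warning in the rare case the empirical AUC still lands below 0.5).
  AUC is the trapezoid area, identical to the Mann–Whitney U/(n₁n₂)
  identity, which the tests assert on random data. Candidate cutoffs are
  midpoints between adjacent unique values (scanner-unit agnostic; observed
  values give the same confusion matrices); the reported cutoff maximizes
  Youden's J = sensitivity + specificity − 1, ties broken toward higher
  sensitivity. `run_full_analysis()` runs ROC for every index significant
  at α between the positive group and each comparison group.

## A worked run

```{r example, eval = FALSE}
cfg <- default_cohort_config()
cohort <- generate_cohort(cfg, mode = "image", seed = 42)
report <- run_full_analysis(cohort, positive_group = "MSA-P")
print(report)
write_report(report, "ln-report")
```

Under the binormal model the expected AUC for two normal classes is
Φ(|μ₁ − μ₂| / √(σ₁² + σ₂²)); at the configured MSA-P/PD corrected-short-line
parameters that is Φ(2.82/2.447) ≈ 0.875, and the simulation targets in
`scripts/acceptance.R` recover it empirically at n = 10⁵ per group.

## Problem sizes and numerical choices

Simulation-backed checks use sizes chosen to keep sampling error well below
the asserted tolerances: 10⁵ per group for binormal AUC recovery (SE ≈
0.001), 10⁴ subjects for generator-mean convergence, 2 × 10³ subjects for
ICC recovery within ±0.05, 100 replicate studies for the index-selection
majority check. Latent redraw loops error after 100 attempts (infeasible
geometry) rather than looping forever; zero-variance inputs to ICC and
single-valued ROC inputs are errors, single-pixel ROI SDs are 0 with a
warning.

## Limitations

The generator is a methods testbed, not an anatomy simulator; distribution
parameters are group-level summaries, so subject-level covariance between
indices (e.g. SL with area) is not reproduced beyond what the shared latent
structure implies. The published patient-level results that depend on the
unavailable raw measurements (inter-rater ICC levels, exact empirical
cutoffs) can only be emulated, not reproduced.
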