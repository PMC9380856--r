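Package: lentimorph
Title: Lentiform Nucleus Morphometry on Susceptibility-Weighted MRI Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Diametral chord morphometry of the lentiform nucleus on axial
    susceptibility-weighted MRI slices, for discriminating the parkinsonian
    subtype of multiple system atrophy from Parkinson's disease. Provides a
    synthetic phantom and cohort generator with closed-form ground truth,
    chord/area/intensity measurement from binary region-of-interest masks,
    corrected bilateral indices with cerebrospinal-fluid intensity
    normalization, and the accompanying statistical battery: normality-gated
    group comparisons (one-way ANOVA with LSD post hoc, or Mann-Whitney U),
    two-rater intraclass correlation with agreement bands, and ROC analysis
    with Youden-index cutoffs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    RNifti,
    stats,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
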