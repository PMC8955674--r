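Package: murihrv
Title: Murine ECG Heart Rate Variability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: End-to-end analysis of single-channel mouse electrocardiograms
    for heart rate variability (HRV) studies: zero-phase Butterworth
    conditioning, a Pan-Tompkins style R-peak detector tuned to rodent
    heart rates, R-R interval windowing and artifact screening,
    time-domain (mean RRI, RMSSD, pNN5) and frequency-domain (LF, HF,
    LF/HF via cubic-spline tachogram and Welch spectra) metrics with
    mouse-specific frequency bands, a four-category welfare/pain scoring
    rubric, and nonparametric group comparison (Mann-Whitney,
    Kruskal-Wallis with Bonferroni post hoc). Includes a synthetic
    mouse-ECG and RR-interval generator with known ground truth for
    validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
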