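Package: sdss
Title: Sub-Array Spatial-Smoothing Adaptive Beamforming for Lung Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the SDSS ultrasound image reconstruction algorithm:
    sub-array decomposition of a uniform linear array, forward/backward
    spatial-smoothing covariance estimation, and minimum-variance
    (Capon) adaptive beamforming with diagonal loading, alongside a
    delay-and-sum baseline and simplified Wiener and SNR post-filter
    comparators. Includes the normalized mean square distance, normalized
    mean absolute distance and PSNR reconstruction-quality metrics, a
    synthetic narrowband echo and phantom simulator for testing without
    clinical data, and a twelve-zone lung ultrasound score cohort model
    with group-level statistics (proportions, means, Welch tests, one-way
    ANOVA with Bonferroni-adjusted pairwise comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    yaml,
    png
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
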