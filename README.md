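# sdss

Adaptive ultrasound image reconstruction by **s**ub-array
**d**ecomposition and forward/backward **s**patial **s**moothing (SDSS),
with the reconstruction-quality metrics and lung-ultrasound-score cohort
statistics used to evaluate it. The package is aimed at people studying
adaptive beamforming for lung ultrasound — where coherent reverberation
artifacts (B-lines, mirror echoes) defeat both conventional delay-and-sum
and naive Capon beamforming — and at anyone who needs a fully synthetic,
reproducible test bench for that processing chain.

## What it computes

For an M-element uniform linear array observing narrowband snapshots
`x(t) = A s(t) + n(t)`:

1. sample covariance `R = (1/T) Σ x(t) x(t)ᴴ`;
2. forward spatial smoothing: the average of the q overlapping `l × l`
   diagonal blocks of `R`, `l = M − q + 1`;
3. backward smoothing: the same block average of the exchange-conjugate
   `J R* J`;
4. forward-backward average `R_s = (R^f + R^b)/2` — persymmetric,
   positive semidefinite, and rank-restoring for coherent arrivals;
5. minimum-variance distortionless (Capon) weights with diagonal loading
   `w = (R_s + εI)⁻¹ a / (aᴴ (R_s + εI)⁻¹ a)`, output power `wᴴ R_s w`
   per look direction.

Reconstructions are scored with the normalized mean square distance
`l = sqrt(Σ(t−r)² / Σ(t−t̄)²)`, the normalized mean absolute distance
`f = Σ|t−r| / Σ|t|`, and `PSNR = 10 log₁₀(max² / MSE)`. The cohort module
models the twelve-zone lung ultrasound score as a continuous 0–100 index,
simulates group-structured cohorts from published group means and SDs,
and reproduces the group-level statistics (proportions, means ± SD, Welch
tests, one-way ANOVA with Bonferroni-adjusted pairwise comparisons).

## Worked example

```r
library(sdss)

# Two-point scene: 32-element half-wavelength array, 8 sub-arrays,
# 200 snapshots at 20 dB SNR, scanned over ±60 degrees.
tab <- run_comparison(default_run_config(seed = 0))
print(tab, digits = 4, row.names = FALSE)
#>       method metric_l metric_f      mse psnr_db width_3db_rad
#>          das   2.1539   11.039 0.050698   12.95      0.056215
#>    mvdr_sdss   0.7157    4.891 0.005597   22.52      0.008458
#>  wiener_post   2.0549    8.790 0.046143   13.36      0.054670
#>     snr_post   2.0242    7.212 0.044776   13.49      0.054453
```

Against the ideal point-target spectrum, the adaptive SDSS scan has a
3× smaller normalized mean square distance than delay-and-sum, ~10 dB
higher PSNR, and a −3 dB mainlobe nearly 7× narrower; the generic Wiener
and SNR post-filters sharpen delay-and-sum only marginally.

```r
cohort <- simulate_cohort(lus_group_specs("s"), seed = 1)
summarize_groups(cohort)
#>   stratum label  n proportion  mean   sd
#> 1       s    S1 74      56.06 41.64 6.62
#> 2       s    S2 58      43.94 28.70 4.90
compare_groups(cohort, "s")
#> Welch two-sample t-test
#> statistic = 12.89, p = 5.53e-25
#>   S1: n = 74, 41.64 +/- 6.62
#>   S2: n = 58, 28.70 +/- 4.90
```

A synthetic 132-neonate cohort at the published respiratory-status group
parameters (S1: n = 74, 40.62 ± 7.22; S2: n = 58, 28.47 ± 6.29)
reproduces the published proportions exactly (56.06% / 43.94%) and the
group difference decisively (P ≪ 0.05).

A command-line wrapper with `simulate`, `beamform`, `metrics`, `cohort`
and `compare` subcommands is installed at
`system.file("scripts/sdss.R", package = "sdss")`. The methods vignette
(`vignettes/sdss-methods.Rmd`) documents the model, parameter defaults,
numerical choices and limitations.

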