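# metartiq

Objective quantification of metal artifacts in CT volumes around
high-density implants — built for protocol optimization around the titanium
pump of a left-ventricular assist device (LVAD), where streaks, noise and
blooming degrade exactly the cardiac and pulmonary anatomy the scan is
meant to show — together with the statistical layer of a visual-grading
observer study.

## What it computes

Three objective artifact measures:

* **ROI metrics** — `Diff_HU = mean(artifact ROI) − mean(reference ROI)`
  (signed, "metal minus normal") and `SD_ARTIFACT`, the sample SD inside
  the artifact ROI.
* **Fourier streak statistic** — HU values sampled at N = 141 arc-length-
  equidistant points along a closed contour surrounding the metal are
  Fourier transformed; `AmplitudeLowFreq = |X₁| + |X₂|` (band 0–2/141 ≈
  0.0142 cycles/sample, DC excluded), averaged over three sequential
  slices with its coefficient of variation.
* **Blooming volume** — `BloomVol`: voxels in an HU band (default
  800–32762) are segmented, the largest 26-connected 3-D component kept,
  and its volume integrated in cm³; apparent enlargement of the implant
  inflates this above the implant's true volume.

Observer-study statistics: score tallying (readers scoring ≥ 3 per
question, summed to `VG_SUM`), inter-reader ICC(C,k) and intra-reader
ICC(A,k) with F-based tests and confidence intervals, baseline-category
multinomial logit models of the ordinal scores
(`ln P(s)/P(1) = β₀ₛ + x'βₛ`), Spearman correlation matrices with
pairwise-complete deletion, and (log-)linear regression of each metric on
acquisition/reconstruction covariates with stepwise-AIC selection and
percent-change coefficient reporting (`(e^β − 1)·100` under the log link).

A synthetic phantom generator produces CT volumes with a cylindrical
implant of known volume, controllable blooming (Gaussian blur scale),
angular streak modulation with a known spectrum, and Gaussian noise, plus
simulated ordinal reader scores with a known latent structure — ground
truth for validating every estimator. Two per-case study tables (36
phantom reconstruction cases, 27 in-vivo reconstructions of one LVAD
patient) are bundled, checksum-pinned.

## Worked example

```r
library(metartiq)

spec <- phantom_spec(seed = 7)          # thorax-like phantom, defaults
g <- generate_phantom(spec)
g$volume
#> <ct_volume> 40 x 64 x 64 voxels (slice x row x col), spacing 1 x 1 x 1 mm
#>   HU range [-1089.3, 3053.1], origin (0, 0, 0) mm
round(g$true_volume_cm3, 2)             # analytic implant volume
#> [1] 7.54

compute_bloom_vol(g$volume, lower = 800)
#> <bloom_result> 8.209 cm^3 (8209 voxels, band [800, 32762] HU)
```

The segmented volume (8.21 cm³) exceeds the true implant volume (7.54 cm³)
because the default 0.8 mm blur pushes the 800 HU boundary outward — that
excess *is* the blooming artifact.

```r
compute_amplitude_low_freq(g$volume, center_slice = 19)
#> <streak_result> AmplitudeLowFreq = 39305.9 (CV 0.5%; slices: 39171, 39193, 39553)
```

With the default 60 HU order-2 streak switched off the same phantom gives
35431.8: the difference is the streak contribution, while the bulk of the
low-frequency amplitude comes from the lung ellipses crossing the contour.
The metric is designed to compare reconstructions of the *same* anatomy,
where the anatomical term is constant.

```r
art <- roi_spec(19, "circle", center = c(31.5, 17), size = 2.5)
ref <- roi_spec(19, "circle", center = c(31.5, 8),  size = 2.5)
compute_roi_metrics(g$volume, art, ref)
#> <roi_metrics> diff_hu = -7.0 HU, sd_artifact = 14.0 HU (n = 22 / 22 voxels)
```

Lung in a dark streak lobe near the implant reads 7 HU below lung farther
away — the signed "metal minus normal" convention.

```r
fx <- load_fixture("patient")
cm <- spearman_matrix(fx$records, c("vg_sum", "bloom_vol", "amplitude_low_freq"))
cm
#> <correlation_matrix> Spearman rho (pairwise complete):
#>                    vg_sum bloom_vol amplitude_low_freq
#> vg_sum              1.000    -0.402             -0.477
#> bloom_vol          -0.402     1.000              0.119
#> amplitude_low_freq -0.477     0.119              1.000
```

Higher blooming volume and higher low-frequency streak amplitude both go
with worse visual grading (negative rank correlations), the blooming and
Fourier metrics being the two that track readers best in the in-vivo
table.

A thin CLI over the same functions is installed at `inst/cli/metartiq`
(`metrics`, `correlate`, `icc`, `regress`, `reproduce`, `validate`).

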