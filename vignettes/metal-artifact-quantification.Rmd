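---
title: "Quantifying metal artifacts around an LVAD implant in CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying metal artifacts around an LVAD implant in CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metartiq)
```

## The problem

The titanium pump of a left-ventricular assist device (LVAD) is a massive,
dense object sitting directly on the cardiac apex. In CT it produces three
families of artifacts that degrade exactly the anatomy a clinician needs:
dark/bright streaks radiating through lung and myocardium, photon-starvation
noise, and *blooming* — the apparent enlargement of the metal itself, which
swallows the inflow cannula lumen and the neighbouring tissue. Protocol
optimization (tube voltage, dose steering, reconstruction kernel, virtual
mono-energetic level, metal-artifact-reduction preset, slice thickness)
requires artifact measures that are objective, reproducible and sensitive to
those parameters, alongside the visual grading that radiologists provide.

`metartiq` implements the three objective measures, the observer-study
statistics used to relate them to visual grading, and a synthetic phantom
generator that provides ground truth for validating every estimator.

## The three artifact metrics

**ROI metrics.** `compute_roi_metrics()` returns
$\mathrm{Diff_{HU}} = \bar{x}_{\text{artifact}} - \bar{x}_{\text{reference}}$
(signed, "metal minus normal": dark streaks in lung give negative values
when the reference is artifact-free lung) and
$\mathrm{SD_{ARTIFACT}}$, the sample standard deviation inside the artifact
ROI. Both use caller-supplied ROIs because physically meaningful placement
("where the artifact is most pronounced") is a judgement the software should
not make. ROIs are circles or rectangles in 0-based voxel coordinates and
must contain at least two voxels so the SD is defined.

**Fourier streak statistic.** Streaks alternate bright and dark around the
metal, i.e. they modulate attenuation at *low angular frequency* along any
closed path surrounding the implant. `extract_metal_contour()` thresholds
the slice (default 800 HU, the same bound the blooming segmentation uses,
so one metal definition serves both), keeps the largest in-slice region,
dilates it by `offset_voxels` (default 3) and traces the sub-voxel
iso-level-0.5 boundary by marching squares. The trace is oriented
counter-clockwise, started at the minimal-(row, col) vertex, and resampled
by arc length to exactly $N = 141$ points where HU values are read by
bilinear interpolation. `compute_spectrum()` applies the unnormalized DFT
$X_k = \sum_t h_t e^{-2\pi i k t/N}$, and the per-slice statistic is
$|X_1| + |X_2|$. `compute_amplitude_low_freq()` averages it over three
sequential slices (re-delineating the contour per slice) and reports the
coefficient of variation of the three values.

Why $N = 141$: the metric's frequency band is defined as 0 to
$2/N \approx 0.0142$ cycles per sample, so bin 2 sits exactly at the upper
band edge. Arc-length resampling to a fixed $N$ makes the band independent
of implant size and pixel pitch. Why offset 3: the trace must clear
partial-volume metal voxels (which would add enormous broadband energy)
while staying inside the streak field, which decays over tens of
millimetres; 3 voxels achieves both at typical cardiac reconstruction
pitches, and the offset is a plain argument for other geometries.

The statistic excludes the DC bin, so it is provably invariant to adding a
constant to all samples and to the contour's starting point (a circular
shift changes only DFT phases). For a pure modulation
$A\cos(\theta + \varphi)$ sampled uniformly in arc length on a circular
contour, $|X_1| = AN/2$ exactly — the closed form the test suite pins.

**Blooming volume.** `compute_bloom_vol()` keeps voxels in an HU band
(defaults 800–32762; in-vivo work raises the lower bound to 2500 because
iodine contrast approaches 800), extracts the largest 26-connected 3-D
component, and reports `voxel_count` times the voxel volume in cm³.
Blooming inflates this volume above the implant's physical volume, so the
segmented volume itself is the severity measure. Connectivity is fixed at
26 neighbours; with a solid metal body the choice is immaterial, but it is
stated so results are auditable. Ties between equally large components are
broken deterministically toward the component appearing first in raster
order.

## The observer-study statistics

**Tallying.** Six questions are graded 1–5 per case and reader;
`tally_scores()` counts readers scoring ≥ 3 per question ($q_1..q_6$) and
sums them to `vg_sum` (0–36 with six readers). Missing readings are counted
over the available readers and flagged, never imputed.

**ICC.** `icc_inter()` is the two-way random-effects, average-measures
*consistency* form $(MS_R - MS_E)/MS_R$: systematic reader offsets are
absorbed by the rater effect, which is the right notion when readers use
the scale with different strictness. `icc_intra()` is the *absolute
agreement* form $(MS_R - MS_E)/(MS_R + (MS_C - MS_E)/n)$ for repeated
readings, where a systematic shift between occasions must count against
reliability. The p-value in both cases comes from $F = MS_R/MS_E$ with
$(n-1, (n-1)(k-1))$ df; confidence intervals invert that F statistic
(consistency) or use the Satterthwaite single-measure construction stepped
up by Spearman–Brown (agreement). Between-case variance of exactly zero is
reported as ICC 0 with a `degenerate` flag rather than 0/0.

**Multinomial logit.** `fit_ordinal_model()` fits the baseline-category
model $\ln P(\text{score}=s)/P(\text{score}=1) = \beta_{0s} + x'\beta_s$
via `nnet::multinom`, with iMAR `None`, keV `40` and kernel `Qr36f` as
reference levels (coefficient 0 by construction). Each reader×case score is
one observation with no reader term — the unit-of-analysis choice is
documented here precisely because pooled readers and reader-stratified
models give different standard errors; the pooled form matches how the
tallied study data are structured. Categories never observed are excluded
with a warning rather than silently carried as unestimable rows, and
coefficients beyond ±15 on the logit scale are flagged as practically
unbounded (complete separation).

**Spearman matrices.** `spearman_matrix()` uses average ranks for ties,
pairwise-complete deletion (so the one phantom case with a missing blooming
volume costs only its own pairs), and two-sided p-values from the
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation with no multiplicity
correction — each cell is reported raw, as observer studies conventionally
tabulate them.

**Metric regressions.** `fit_metric_model()` fits the metric on the
covariates by OLS, either linearly or as a power law (log response, log
numeric covariates, dummy-coded factors), optionally with bidirectional
stepwise AIC starting from the main-effects model; interactions are only
eligible while both parents are present. Under the log link,
`coefficients_as_percent_change()` converts a coefficient to
$(e^{\beta}-1)\times 100$ percent. A signed response (phantom
$\mathrm{Diff_{HU}}$ is negative) is fitted on its absolute value under the
log link and the convention is recorded in the fit object. The numeric-keV
mode (`vmi_coding = "numeric"`) drops poly-energetic reconstructions (T3D)
and the spectral post-processing level (SPP-70) because they have no
defensible single keV value; consequently the package does not claim to
reproduce published adjusted-R² values that depend on some unstated numeric
encoding of those levels.

## The synthetic phantom: what it emulates and what it does not

`generate_phantom()` composites, on a thorax-like background (air, body
ellipse at 40 HU, two lung ellipses at −750 HU):

* a cylindrical implant (default r = 10 mm, h = 24 mm, 3000 HU — a titanium
  body with partial saturation) whose true volume $\pi r^2 h$ is known
  analytically;
* **blooming** as a Gaussian blur (default σ = 0.8 mm) of the implant
  indicator before compositing. At the 800 HU threshold — about a quarter
  of the edge height — the apparent boundary moves outward monotonically
  with σ, which reproduces the threshold-dependent enlargement with one
  interpretable parameter;
* **streaks** as sinusoidal bright/dark modulation
  $A\cos(m\theta + \varphi)e^{-d/\lambda}$ outside the implant (defaults
  A = 60 HU, order m = 2, decay λ = 40 mm). This is deliberately *not* a
  physical beam-hardening simulation: the Fourier metric senses only the
  angular frequency content along the contour, so a low-order sinusoid is
  the minimal model that exercises it with a known spectrum;
* **noise** as i.i.d. Gaussian voxel noise (default 15 HU).

All randomness flows through one integer seed per operation; the caller's
RNG state is untouched. What the generator does **not** emulate: correlated
reconstruction noise, beam-hardening physics, motion, partial-volume
spectra, or anatomically realistic texture. Passing the synthetic battery
therefore demonstrates that the *estimators* are correct and sensitive in
the documented directions — not that any particular clinical protocol is
optimal.

`simulate_reader_scores()` draws scores by discretizing a per-case latent
quality plus reader noise through four ordered cutpoints. Discretization
*attenuates* the intraclass correlation of the observed scores below the
latent-model value, so recovery tests compare against the population ICC of
the discretized scores, computed by 1-D Gaussian quadrature over the latent
variable (`icc_ck_discretized`, cross-checked by Monte Carlo) — comparing
against the latent ICC would build a known bias into the test.

## Numerical choices and degenerate inputs

* Sample (n−1) standard deviations throughout, including the CV of the
  three per-slice streak values.
* Bilinear interpolation for contour HU samples; marching squares
  (`grDevices::contourLines` at level 0.5) for the sub-voxel boundary.
* Contours touching the image border, slices without metal, empty
  threshold bands, constant columns in correlation, zero between-case
  variance in ICC, and rank-deficient regression designs are all explicit
  errors or flagged results, never silent numbers.
* 3-D labelling uses vectorized min-label propagation to a fixed point;
  component identity is the smallest raster-order linear index, making
  tie-breaks deterministic.
* NIfTI headers store float32 spacings; round-trip tests therefore compare
  spacing at 1e-6 while voxel data round-trip bitwise (written as float64).
* DICOM support covers uncompressed explicit-VR little-endian series — the
  axial export format of the relevant scanners; sequences and compressed
  transfer syntaxes are rejected with clear errors rather than half-parsed.

## The bundled study tables and what reproduces

Two per-case tables ship with the package (`load_fixture()`): 36 phantom
reconstruction cases and 27 in-vivo reconstructions of one LVAD patient,
with covariates, the four metrics, per-question tallies and `vg_sum`. They
are checksum-pinned; iMAR abbreviations (`Pa`, `Tc`, …) expand through a
fixed dictionary, and one keV label that appears in two spellings in the
printed sources is normalized to `SPP-70`.

Internal consistency holds row by row (`vg_sum` equals the tally sum for
all 63 cases), and `run_study_reproduction()` reproduces the published
extrema exactly (phantom VG_SUM maximum 25, in-vivo 14; blooming volume
42.3–92.7 cm³ phantom, 27.0–96.3 cm³ in vivo). Spearman cells computed
purely among visual-grading columns reproduce the published in-vivo
coefficients to all three printed decimals, which validates both the
transcription and the tie/deletion conventions. Cells involving the
objective metrics, however, deviate by up to ~0.07 from the published
values: the study's correlation analysis evidently ran on unrounded
per-case metric values (and the published p-values are not internally
consistent with the printed coefficients at the printed sample sizes under
any standard approximation), so those exact cells cannot be recovered from
the printed, rounded tables. The package reports what the bundled data
actually give; the corresponding acceptance checks are left failing rather
than loosened, with the computed values written by
`scripts/acceptance.R` for comparison.

## Problem sizes used in validation

The test battery uses 32–40-slice volumes with 48×48 in-plane voxels at
1 mm pitch (large enough that cylinder voxelization error is below 1%,
small enough that the whole suite runs in about a minute), 5-point sweeps
for monotonicity/linearity properties, 100 simulation replicates at 100
cases for ICC recovery, and 5×500 observations for multinomial coefficient
recovery — sizes chosen so sampling error is comfortably inside each
property's tolerance.

## Known limitations

* ROI placement and the choice of representative slices are manual by
  design; the package quantifies, it does not localize.
* The Fourier statistic assumes a single dominant metal object; multiple
  implants in one slice are traced around the largest only.
* The blooming metric depends on the lower HU threshold when contrast
  agent or bone approaches the band; the threshold is a reported parameter
  of every result, not a hidden constant.
* Inter-reader ICC values for the bundled tables cannot be recomputed
  (per-reader raw scores were never published); the ICC implementation is
  validated on synthetic readers instead.
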