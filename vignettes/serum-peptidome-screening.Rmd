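---
title: "Serum peptidome biomarker screening: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum peptidome biomarker screening: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maldiscreen)
```

## The problem

Low bone mass (osteopenia) precedes osteoporosis and is clinically silent;
a serum assay that flags it early would be valuable because dual-energy
X-ray absorptiometry is a lagging indicator. One established discovery
route is peptidome profiling: enrich the low-molecular-weight serum
fraction (e.g. on weak cation-exchange magnetic beads), acquire MALDI-TOF
spectra per subject, and look for m/z features whose intensity
discriminates cases from controls. `maldiscreen` implements that entire
computational workflow — from raw two-column spectra to a cross-validated
classifier and candidate protein identities — together with a synthetic
cohort generator that reproduces the statistical structure of a published
two-group osteopenia study (10 cases, 10 controls, ~133 peaks between
1000 and 20000 Da, markers at 1699 Da up in cases and 3038 Da down in
cases, the latter attributed to secretin), so every stage can be exercised
and tested without access to the original serum data.

## Pipeline model

The stages run in a fixed order; each is exported on its own.

### 1. Denoising (stationary wavelet transform)

Instrument noise is removed with an undecimated (a trous) Daubechies-4
wavelet decomposition, 5 levels by default, with circular boundary
handling. Detail coefficients are soft-thresholded at the universal
threshold

$$\lambda = \hat\sigma \sqrt{2 \log N}, \qquad
  \hat\sigma = \mathrm{median}(|d_1|)/0.6745,$$

where $d_1$ is the finest detail level. The undecimated (shift-invariant)
variant is essential for spectra: peak positions must not move. The
transform with thresholding disabled is exactly invertible (tested to
1e-8 relative error), which pins down the filter bank implementation. The
wavelet family and level count are conventional defaults for MS denoising
and are exposed in `preprocess_config()`.

### 2. Baseline removal

The chemical background is estimated as a moving minimum over a +/-200 Da
window followed by a moving average of the same window, and subtracted
with clipping at zero. This estimator is transparent and testable (on a
gentle ramp it recovers the trend up to a systematic `slope * window`
underestimate, which only makes the baseline sit safely below the
signal). Its residual error behaves like curvature x window^2; where the
baseline decays fast the residual leaves small (<~10 intensity-unit)
smooth humps — see *Known limitations*.

### 3. Low-mass crop

The source protocol states a 2000 Da raw-data cutoff yet reports features
over 1000–20000 Da including a 1699 Da marker — an internal
inconsistency. The package supports both readings; the default cutoff is
1000 Da so that the reported marker range is reproducible, and `2000` is a
single config change.

### 4. Normalization

"Uniform" per-sample intensity treatment is interpreted as total ion
current (TIC) normalization: each spectrum is scaled so its TIC equals
the cohort mean. Scale pairs become identical and all TICs agree after
the call.

### 5. Peak detection

Apexes are strict local maxima of the preprocessed signal. Each apex is
scored by a signal-to-noise ratio and kept when SNR >= 3. The noise level
is a rolling robust scale estimate — MAD/0.6745 within a +/-250 Da window,
median-centred (which removes the local trend), evaluated on a stride and
interpolated. In the assembled pipeline the SNR denominator is estimated
on the *raw* baseline-subtracted signal rather than the denoised one:
denoising removes precisely the noise that the ratio should reference, so
the post-denoise residual would understate it and admit hundreds of
artifact apexes. This is the convention of established MS peak pickers.

### 6. Cross-sample clustering and prevalence filter

Peaks from all samples are pooled, sorted by m/z, and grouped greedily: a
peak joins the open cluster iff its distance to the cluster's running
representative (the intensity-weighted mean m/z of its members) is below
0.3% of that representative. Anchoring the tolerance at the
representative — not the nearest member — prevents single-linkage
chaining, where runs of closely spaced artifact apexes would bridge two
genuine features; in development this chaining measurably pulled
representatives off the true peak positions, and the representative-anchored
rule recovers every generated peak. A cluster keeps at most one peak per
sample (the most intense; a displaced peak becomes a singleton cluster,
which the prevalence filter then usually removes). Clusters present in
fewer than 10% of samples are dropped; exactly 10% survives, because the
removal rule is "fewer than 10%".

### 7. Univariate screening

Each cluster is tested case-vs-control with the Wilcoxon rank-sum test
(exact enumeration when the pooled size is at most 12 with no ties,
otherwise the normal approximation with tie and continuity corrections).
Features with raw p < 0.05 survive; no multiplicity correction is applied
by default, mirroring the original raw-P screening (a Benjamini–Hochberg
switch exists). The reported direction in cases comes from group medians —
the location summary consistent with a rank test — with group means
reported alongside.

### 8. Classification (GA-wrapped SVM, LOOCV)

The classifier is a C-SVM with radial kernel at the study's fixed
hyperparameters, gamma = 0.6 and C = 19. Intensities (in the hundreds)
would make that kernel degenerate, so features are z-scored inside each
training fold; the held-out sample never contributes to the
standardization or the fit (fold hygiene is tested directly against a
manual per-fold oracle). Feature subsets are searched by a small genetic
algorithm over binary masks: population 50, 40 generations, tournament
selection of size 2, uniform crossover (rate 0.8), per-bit mutation
(rate 0.05), subset sizes constrained to 2–5, one elite carried per
generation (so the best-fitness trace is non-decreasing), fitness =
leave-one-out accuracy of the masked SVM (LOOCV Youden index is the
alternative). Fitness ties prefer smaller subsets, then lower summed m/z,
making the search deterministic under a seed; fitness values are memoized
per subset. These GA settings are desk-scale and are validated against
exhaustive pair search on 10-candidate problems. The final model is
refit on all samples and reported with per-sample scatter coordinates:
the first principal component of the standardized selected submatrix
against the SVM decision value (oriented so positive = case).

The marker-quality score used for ranking is the Youden index
$J = \text{sensitivity} + \text{specificity} - 1$; `best_cut()` scans all
midpoints between sorted unique values in both orientations and ties
break toward the lower threshold.

### 9. Candidate identity lookup

An observed peak mass is matched against a protein record table within a
fractional mass window $m(1 \pm 0.003)$ and a pI window [4, 14], ranked
by absolute mass difference. Average (not monoisotopic) residue masses
are used, appropriate for singly charged peptides in this range. pI is
computed from a fixed Bjellqvist-style pK table (C-terminus 3.55, generic
N-terminus 7.50; side chains D 4.05, E 4.45, H 5.98, C 9.0, Y 10.0,
K 10.0, R 12.0) by bisection on the monotone net-charge function to
|charge| < 1e-6. Published pI values from other tools can differ by small
pK-table effects, so sequence-derived pI is compared at +/-0.3. The
packaged peptide-hormone table is a *constructed* fixture (literature
average masses and pI values), not a database snapshot; its secretin row
stores the published record values (Mw 3040 Da, pI 9.46) as
authoritative, with the mature-chain sequence included only as an
external-sourced cross-check.

## The synthetic cohort generator

`make_cohort()` draws, once per cohort, ~133 peak positions (uniform over
the grid with at least 0.8% mutual separation so features stay resolvable
at the 0.3% clustering tolerance) and lognormal base amplitudes
(meanlog log(200), sdlog 0.5, similar in scale to the published marker
intensities). Per sample, null-peak amplitudes get multiplicative
lognormal jitter (sdlog 0.25) so clustering and prevalence filtering are
non-trivial; the two discriminating peaks draw their amplitudes from the
published group-specific normal distributions (1699 Da: 299.04 +/- 140.72
cases vs 164.32 +/- 105.04 controls; 3038 Da: 383.78 +/- 332.46 vs
649.97 +/- 236.04). Peaks are Gaussian with sigma = mz/2000 (a crude
constant-resolution model), the baseline decays exponentially
(amplitude 100, decay 5e-4 per Da), noise is additive Gaussian
(SD 5), and negative draws are clipped at zero — intensities are
physical, and clipping preserves the configured moments better than
rejection sampling for the strongly left-truncated 3038 Da case group.
The grid is 1000–20000 Da in 0.5 Da steps. ELISA concentrations and the
demographic covariates (age, weight, height, menopause duration) are
generated from the published group summaries; demographics are
descriptive only and never influence the spectra.

What the generator does *not* emulate: isotope envelopes, adducts,
matrix cluster ions, detector saturation, mass-calibration drift between
samples, heteroscedastic (intensity-dependent) noise, or correlated
biological covariation between peaks. Passing tests therefore demonstrate
the pipeline's statistical and numerical behaviour under the idealized
generative model, not performance on real serum spectra.

A diagnostic note on power: with the published group means/SDs at
n = 10 + 10, a two-sample comparison has modest power, e.g.

```{r, eval = FALSE}
power.t.test(n = 10, delta = 299.04 - 164.32,
             sd = sqrt((140.72^2 + 105.04^2) / 2))$power
power.t.test(n = 10, delta = 649.97 - 383.78,
             sd = sqrt((332.46^2 + 236.04^2) / 2))$power
```

so a Wilcoxon screen at p < 0.05 retains each marker only part of the
time, and both-markers-jointly less often still. The acceptance suite
measures these retention rates over replicated cohorts; single-cohort
runs (like the original study) should be read with that sampling
variability in mind.

## Numerical choices

* Circular (periodic) boundary handling in the wavelet transform — exact
  reconstruction at any signal length, not only powers of two.
* The moving minimum uses a two-block sparse-table construction and the
  moving average a cumulative sum, both O(n), with edge replication.
* Rolling MAD is evaluated every half-window and linearly interpolated.
* Degenerate inputs: zero-TIC spectra, over-cropping, empty cluster sets,
  single-class training folds, zero-SD summary pairs (t = 0 by
  convention when means agree) and illegal residue codes are all
  rejected with named errors.
* One master seed fans out to per-stage seeds through a documented
  linear-congruential hash (`derive_seed()`), so stages are independently
  reproducible and a full run is bitwise reproducible from
  `(config, seed)`.
* Test problem sizes were chosen desk-scale: 200 replicated cohorts for
  the screening study, 20 for end-to-end runs, 100k-point signals for the
  denoiser checks.

## Known limitations

* Soft-thresholding narrow, under-resolved peaks (sigma of 1–2 grid
  points at the low-mass end) leaves small ringing sidelobes, and the
  baseline estimator leaves smooth residual humps where the background
  curves quickly. Both produce low-intensity artifact clusters — the
  feature matrix typically carries ~20–30% more rows than true peaks,
  all at intensities an order of magnitude below genuine features. All
  generated peaks are still recovered; downstream screening is diluted
  but not biased.
* The screening stage inherits the small-sample power limits described
  above; with n = 10 + 10 at the published effect sizes, joint retention
  of both markers is well below certainty.
* LOOCV accuracy of a model selected *after* screening on the same
  cohort is optimistically biased (selection bias); the package reports
  it because the emulated workflow does, but the chance-level and
  separable-limit tests are the properties actually asserted.
* `best_cut()` reports no confidence interval for J, and the pipeline
  performs no mass recalibration/warping between samples beyond the
  clustering tolerance.
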