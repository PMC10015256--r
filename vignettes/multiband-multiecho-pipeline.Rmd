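---
title: "Multiband multi-echo resting-state connectivity: methods and phantom validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiband multi-echo resting-state connectivity: methods and phantom validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mefc)
```

## What the package models

Multiband (MB) EPI shortens the repetition time by exciting several slices at
once; multi-echo (ME) EPI acquires several echo times per excitation. A
combined MBME acquisition permits voxelwise estimation of the effective
transverse relaxation time T2\* and an echo combination that weights each
echo by its expected BOLD sensitivity. `mefc` implements the downstream
resting-state analysis chain for both acquisition styles: echo combination,
standard denoising, seed-based and ROI-based functional connectivity,
functional connectivity density (FCD) mapping, test–retest reproducibility
metrics, and a group comparison layer — all driven by a synthetic phantom
generator so that every stage is testable without scanner data.

## The phantom generator

Real two-visit MBME studies are rarely shareable, so the generator emulates
one: an MB-like acquisition (TR 650 ms, TE 30 ms, 554 volumes for a
six-minute run) and an MBME-like acquisition (TR 900 ms, TE 11/30/49 ms,
400 volumes), 29 subjects of whom 18 return, for 47 sessions
(`study_design()`).

The anatomy is an ellipsoidal brain with a CSF shell, a GM shell and a WM
core; GM is partitioned into contiguous parcels by seeded multi-source
region growing. Each voxel carries ground-truth T2\* (GM 30–60 ms, with an
inferior "dropout" cap at 15–25 ms mimicking susceptibility regions) and an
equilibrium signal S0. The signal model per brain voxel is

$$S_v(t, TE) = S0_v\, e^{-TE \cdot R2^*_v(t)}\,\bigl(1 + d_v(t) + p(t)\bigr) + \varepsilon_v(t),$$

with $R2^*_v(t) = 1/T2^*_v + (A/T2^*_v) \sum_k L_{vk} n_k(t)$. The latent
network signals $n_k$ are unit-variance Gaussian processes with a requested
cross-correlation, temporally smoothed to concentrate power in the classical
resting-state band. Two properties of this construction matter:

* **BOLD enters through R2\***, so its amplitude is TE-dependent. This is
  what makes T2\*-weighted echo combination demonstrably beneficial on the
  phantom, and mirrors the TE-dependence logic that component-based
  multi-echo denoising exploits.
* **Nuisance enters multiplicatively through S0-like terms**: per-voxel
  Legendre drift and globally shared sinusoids at 0.25 and 1.0 Hz (aliased
  as the TR dictates). Drift coefficients are part of the anatomy (scanner
  installation); physio phases are drawn per session (scanner state).

Between-session reproducibility is controlled by a single `session_stability`
parameter $s \in [0, 1]$: timepoint-2 latents are
$s \cdot n^{(1)} + \sqrt{1 - s^2}\, m$ with $m$ a fresh draw from the same
correlation structure, so $s = 1$ reproduces the first session's networks
exactly while preserving the marginal structure at every $s$.

Defaults were chosen once, as plausible study conditions: thermal noise
(`noise_sd = 7` at S0 ≈ 1000) gives per-echo GM tSNR of roughly 50–100,
conventional for 3 mm voxels at 3 T; BOLD amplitude 0.02 (fractional R2\*
modulation, about 1–2 % signal change at TE 30 ms); session stability 0.8.
Motion traces are generated (smooth random walks, ~0.1 mm/0.1°) but motion
is *not* applied to the images — realignment is out of scope, and the traces
exist to exercise nuisance regression and df accounting.

What the phantom does **not** emulate: k-space physics, multiband
unaliasing and g-factor noise amplification, applied head motion, realistic
cardiac/respiratory waveforms, spatial autocorrelation of thermal noise, and
inter-subject anatomical variability beyond RNG draws. Passing tests
therefore demonstrate algorithmic correctness and the direction of
acquisition effects under the stated model, not in-vivo effect sizes.

## Echo combination

`fit_t2star()` performs ordinary least squares of log signal on TE — the
log-linear fit, unweighted by design (no variance weighting), with the
temporal-mean signal per echo as the default input. A per-volume variant
(fit each volume, average the fitted coefficients) is available; for
stationary decay the two agree. T2\* is clamped to [2, 300] ms: zero or
positive slopes (non-decaying voxels) land on the upper clamp, and voxels
with fewer than two positive samples are marked invalid and likewise
assigned the clamp. Both clamp ends are exposed as arguments.

`combine_echoes()` implements the T2\*-weighted scheme with per-voxel
weights

$$w_i = \frac{TE_i\, e^{-TE_i / T2^*}}{\sum_j TE_j\, e^{-TE_j / T2^*}},$$

the standard BOLD-sensitivity weighting. For T2\* = 40 ms and TE 11/30/49 ms
the weights are (0.2263, 0.3838, 0.3899). Because the weights are
normalised to sum to one, the separately named "normalised" variant is the
same operation and is kept as an alias; plain `summation` is also provided.

`tsnr()` is voxelwise mean over sample SD (denominator $N-1$); zero-SD
voxels become `NA`. The time-point adjustment multiplies by
$\sqrt{N_{TP}}$ — the square root is the statistically meaningful scaling
(detection power grows with $\sqrt{N}$ for white noise), and the flag is
named `scale_by_sqrt_ntp` so the convention is explicit at every call site.

## Standard denoising

The chain is discard → combine → smooth → regress (detrend + nuisance in a
single design) → bandpass; the order is configuration-driven because
advanced pipelines reorder smoothing and filtering. Choices that needed
deciding:

* **Initial discard**: `ceil(seconds / TR)` volumes, guaranteeing that at
  least the requested duration (default 10 s) is removed: 12 volumes at TR
  900 ms, 16 at TR 650 ms.
* **Echo combination and discard commute** (the combination weights are
  time-independent), so `run_pipeline()` combines first and discards
  second; the result is identical either way.
* **Detrending lives inside the regression design** as Legendre polynomials
  of orders 0..k, so degrees-of-freedom accounting is unified: df loss =
  motion + tissue + component columns + detrend order, the constant
  excluded. The standard configuration (12 motion parameters, WM, CSF,
  third-order detrend) spends 17 df. Six-parameter motion is also
  supported (11 df); the 12-parameter model adds backward-difference
  temporal derivatives.
* **Bandpass is an ideal spectral mask** retaining bins strictly inside
  (0.01, 0.1) Hz, zero-phase by construction, with the voxel mean restored
  afterwards. An ideal mask makes the pass/stop-band contracts exact and
  testable; the trade-off (ringing at band edges for broadband transients)
  is acceptable for correlation analyses.
* **Smoothing** is a separable Gaussian,
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis in voxel units
  (0.566 voxels for 4 mm FWHM on 3 mm voxels), renormalised over in-mask
  support so constants are preserved and out-of-mask intensities never
  leak in.
* **Tissue regressors** (WM/CSF means) are extracted before smoothing from
  masks eroded by one voxel, falling back to the raw mask when erosion
  would empty it.
* **Component injection**: externally computed component time courses
  (e.g. from ICA-based denoising) enter the same design as extra columns
  and are counted in the df ledger; the package does not classify
  components itself.

Every series carries a `df_ledger`; informational entries (discard,
bandpass bin counts) are excluded from `df_total()`.

## Connectivity and FCD

`seed_map()` correlates the seed-mean series with every in-mask voxel;
zero-variance voxels map to r = 0 (not missing) so downstream counting
stays defined, and are flagged. The effective df is
$N_{TP} - 2 - \text{df loss}$. `roi_matrix()` orders the subcortical block
first, then cortical, each ascending by label. Thresholding is inclusive
(`r >= thr`) everywhere, matching the conventions the analyses are stated
in; matrix diagonals are excluded.

FCD at threshold r ≥ 0.6: `gfcd()` counts, for each voxel, the in-mask
voxels whose series correlate with it at or above threshold (self excluded
by default); `lfcd()` grows a spatially contiguous cluster from the index
voxel, admitting neighbours by their correlation *with the index voxel*
(never chained), and counts the cluster including the index voxel. The
neighbour scheme is 26-connectivity by default with 6/18 available, and
both self-count conventions are exposed — published implementations differ
on both points, and neither is dictated by the defining texts. Correlations
are computed against the index voxel on the fly, so no voxel×voxel matrix
is materialised; correctness is established by exact equality with
brute-force oracles on dozens of random volumes.

## Reproducibility metrics

For thresholded binary results the Dice coefficient
$DC = 2|A \cap B| / (|A| + |B|)$; for symmetric matrices only the strictly
lower triangle enters. Two empty inputs give `NA` — "undefined", reported
distinctly rather than silently 0 or 1. For FCD maps the voxelwise
$\mathrm{REP} = 1 - |x_1 - x_2| / (x_1 + x_2)$, with 0/0 defined as 1 (two
equal values), summarised as a region mean over GM. REP is symmetric and
invariant to positive rescaling of both maps.

## Group layer

`paired_test()` regresses per-element session differences on an intercept
plus a mean-centred covariate (scan number in the emulated design, coded as
the session ordinal); the intercept t with $n - 2$ df tests the adjusted
mean difference, and without a covariate the operation reduces exactly to
the textbook paired t-test. Zero-variance differences are flagged
(t = ±Inf, p = 0) rather than silently propagated. FDR uses the
Benjamini–Hochberg step-up (default q = 0.05; 0.01 available — both levels
appear in practice).

Cluster-extent correction is a transparent Monte Carlo: white Gaussian
volumes, smoothed to the requested FWHM, standardised in-mask, thresholded
two-sided at the voxel p, largest 26-connected cluster recorded per
iteration, minimum cluster size = ceiling of the $1-\alpha$ quantile. This
deliberately replaces autocorrelation-function-based simulators: it is
simple, seeded and auditable, but it is **not** numerically equivalent to
them, and thresholds from ACF-based tools are not comparison targets.

## Problem sizes and numerical tolerances

The test suite runs the full chain at desk scale: grids of 10–24 voxels per
axis, 20–120 volumes, 2–8 subjects, chosen so the whole suite completes in
well under a minute while still exercising every code path at realistic
parameter values. Exact contracts (mono-exponential inversion, oracle
equality for FCD, df arithmetic, Dice/REP identities) are tested to
1e−6 or exactly; sampling-based properties (planted correlation ± 0.1 at
400 volumes, type-I calibration 4.5–5.5 % at 10,000 null elements,
reproducibility monotone in session stability over five seeds) use bounds
derived from their sampling distributions. Degenerate inputs — constant
series, empty seeds and ROIs, rank-deficient designs, unattainable
thresholds — have defined, tested behaviour rather than incidental output.

## Known limitations

* No realignment, spatial normalisation or atlas support: everything
  operates in phantom/native voxel space on pre-aligned data.
* No multi-echo ICA or motion-component classification; only the injection
  point for their regressors.
* The cluster-extent Monte Carlo assumes Gaussian smoothness.
* `lfcd()` is exact but O(voxels²·time); it is sized for ROI-scale masks
  and desk-scale phantoms, not whole-brain 2 mm grids.
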