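---
title: "Methods: seed-connectivity prediction of tDCS response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-connectivity prediction of tDCS response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `tdcsfc`, the design
choices that were genuinely open, and the limits of what the synthetic
cohorts can demonstrate.

## The prediction problem

Patients with schizophrenia and persistent auditory verbal hallucinations
receive add-on tDCS; response is a ≥ 25% drop (inclusive boundary — "at
least" a quarter) in the total PSYRATS-AH score. The predictor is the
pre-treatment resting-state seed-connectivity map of the left superior
temporal gyrus (LSTG): for each brain voxel $v$, the Pearson correlation
$r_v$ between the voxel's BOLD series and the mean series of a 15 mm sphere
at MNI $(-48, 0, 0)$, variance-stabilized as $z_v = \operatorname{arctanh}
r_v$. The classifier is L1-penalized logistic regression over the $z_v$ of
a-priori regions, evaluated by five shuffled repetitions of stratified
10-fold cross-validation.

## The synthetic generative model

The study cohort is not public, so every stage runs against simulated
cohorts whose structure matches what the analysis assumes.

**Signal model.** Each atlas region $l$ carries a latent unit-variance
AR(1) process $L_l(t)$ with lag-1 coefficient 0.3 (resting-state BOLD is
strongly autocorrelated; white-noise latents would make the band-pass stage
trivial). The seed-home region's latent is $S$. Each *discriminative*
region's latent is replaced by the exact mixture

$$ U = \rho S + \sqrt{1 - \rho^2}\, E, \qquad E \perp S, $$

which has unit variance and $\operatorname{cor}(U, S) = \rho$ by
construction — the closed-form mixing weight needs no calibration loop.
Responders use $\rho = 0.6$, non-responders $\rho = 0.2$, in two
discriminative regions by default. Gray-matter voxels receive their region
latent plus white noise (SD 1) plus a 0.3-weight leak of two shared
nuisance processes; white-matter and CSF voxels carry the nuisance
processes themselves, which is exactly the structure aCompCor assumes.
Motion is drawn as six small rigid-body series; global-signal spikes add a
constant to every in-brain voxel at sampled volumes.

**Geometry.** The default grid is 24 × 28 × 24 at 4 mm isotropic — the same
anatomy at desk scale; `full_scale = TRUE` reproduces the 91 × 109 × 91
ambient grid at 2 mm. The brain is the inscribed ellipsoid; concentric
shells define CSF (innermost), white matter and gray matter. Regions are a
Voronoi tessellation around spread-out centers (cells of a Voronoi
tessellation intersected with a convex body are convex, hence contiguous),
with the first center at the seed coordinate. All voxels within 16 mm of
the seed are assigned to the seed-home region so the default 15 mm seed
sphere never leaks into neighboring regions — mirroring the fact that the
STG seed lies within the STG. Without this guarantee, sphere voxels shared
with a coupled region make the *seed-home* region itself class-informative
(the seed mean then contains coupled signal), which contaminates
attribution.

**Clinical covariates** are drawn independently from truncated normal
distributions with the published group means/SDs (ages truncated to the
18–48 inclusion range, scores to their scale ranges); sex is Bernoulli with
the group male:female ratios (7:10 and 12:5). No covariance structure is
published, so none is imposed. The post-treatment score is derived from a
drawn percent improvement (responders ≥ 25, non-responders < 25), so the
responder rule applied to generated pre/post scores recovers the intended
label with zero mismatches. Note the zero-truncation of wide distributions
(e.g. negative-symptom scores, mean 38.35, SD 20.89) raises group means by
about $\sigma \phi(\alpha) / (1 - \Phi(\alpha)) \approx 1.6$ points; tests
of generator calibration account for this.

**Pre-training cohort.** 186 healthy controls and 62 unaffected
first-degree relatives (CGI fixed at 0) plus 44 schizophrenia and 149 OCD
patients (CGI drawn from {4, 5, 6}) — 441 records. Each record carries a
seed-FC volume derived from a short BOLD series on a reduced grid, with
coupling increasing in CGI, emulating a global illness-severity signal.

**QC fixture.** A 39-subject cohort in which exactly 2 subjects are flagged
as irrecoverable registration failures and exactly 3 carry planted motion
excursions (isolated 3 mm translations at 16 volumes of 100; each excursion
censors its own volume and the return volume, pushing the censored fraction
to 0.32 ≥ 0.30). The violators are planted through *motion* rather than
global-signal spikes deliberately: the scan-to-scan global-signal z is
standardized by the SD of the difference series itself, so spikes dense
enough to censor 30% of volumes inflate that SD and can never reach z = 9,
whereas the 2 mm motion threshold is absolute.

## QC and denoising choices

* **Outlier volumes.** Volume $t$ is censored when the absolute z-score of
  the scan-to-scan global-signal change reaches 9, or composite motion
  reaches 2 mm. The z is computed on the difference series $g(t) - g(t-1)$
  standardized by its own mean and SD ("scan-to-scan global signal
  z-value"); the first volume is never censored by this criterion. A
  consequence worth documenting: a single isolated spike cannot exceed
  $z = \sqrt{(n-1)/2}$ (the spike's two difference entries dominate the
  SD), so the criterion only bites at longer runs — with 300 volumes the
  cap is ≈ 12.2.
* **Composite motion** is not standardized anywhere; we use the maximum
  over the six rigid-body parameters of the scan-to-scan displacement, with
  rotations converted to millimetres of arc on a 50 mm sphere (a common
  convention, and exactly testable).
* **Exclusion** at censored fraction ≥ 30% (inclusive: exactly 30% is
  excluded) or failed registration; registration failure takes precedence
  in the recorded reason. Raising the cutoff can only retain more subjects
  (monotone).
* **aCompCor.** Top 5 principal-component time series from WM and CSF
  voxels separately, computed on non-censored volumes; the confound matrix
  adds the motion parameters, one indicator per censored volume
  (scrubbing-as-regression — the censored volumes are also excluded from
  the later correlation, a belt-and-braces combination) and an intercept.
  Residuals are exact least squares, hence orthogonal to every confound
  column on non-censored volumes to numerical precision (< 1e-8 in tests).
  Requesting more components than the available rank reduces with a
  warning; an empty mask is an error.
* **Detrend → despike → band-pass**, in that order. Despiking winsorizes
  at ±4 SD (a toolbox-agnostic, documented choice; spline-based despiking
  is deliberately not imitated). The band-pass is a zero-phase
  frequency-domain mask on 0.008–0.09 Hz: bin-aligned pass-band tones are
  preserved exactly, stop-band bins are removed entirely, and the filter is
  idempotent in-band. A band edge at or above Nyquist is a configuration
  error.
* **Smoothing** uses the separable Gaussian with
  $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ per axis in voxel units,
  boundary kernels renormalized (constants are preserved exactly); an FWHM
  under half a voxel is the identity.

## Connectivity and features

Sphere membership is by voxel-center distance through the affine (not
any-overlap) — exactly testable against lattice enumeration. Correlations
are clamped to $\pm(1 - 10^{-7})$ before arctanh, so a voxel identical to
the seed mean maps to $z = \operatorname{arctanh}(1-10^{-7}) \approx 8.41$
rather than infinity; zero-variance voxels (background, or constant after
censoring) are assigned $z = 0$ to preserve the fixed-size feature volume.
Fewer than 10 non-censored volumes is an error. Feature order is canonical
— region label ascending, then voxel raster order — regardless of the
order in which region labels are requested; the voxel-index map retains
label and coordinates of every feature for attribution.

## Classification and evaluation

"Default hyperparameters" of the reference implementation map to inverse
regularization strength $C = 1$; on glmnet's mean-loss scale that is
$\lambda = 1/(nC)$. Features are standardized with the *training-fold*
mean/SD (applied unchanged to the test fold): the upstream protocol does
not specify feature scaling, but L1 penalties are scale-sensitive and
Fisher-Z features vary in scale; the behavior is switchable
(`l1_logistic_factory(standardize = FALSE)`).

Stratified folds keep each fold's class counts within one subject of the
cohort ratio *and* fold sizes as even as possible (for 17/17 with 10 folds:
sizes in {3, 4}); a class smaller than the fold count degrades gracefully
(some folds lack the class). Confusion counts are accumulated per
iteration; means and standard errors are reported over the 5 iterations.
Accuracy is reported both as the mean of per-fold accuracies (primary) and
pooled from the iteration confusion counts — the two differ when fold sizes
differ, and the reference tables are consistent with per-fold averaging.
The paired model comparison uses the 50 per-fold accuracies on identical
fold assignments; two identical results define $t = 0, p = 1$ rather than
0/0.

## CNN and transfer learning

The volumetric classifier is implemented in base R (im2col convolution,
ReLU, non-overlapping max pooling, one hidden FC layer with inverted
dropout, softmax cross-entropy, Adam). Backpropagation is verified against
central finite differences to ~1e-10 in tests. The published figure's layer
hyperparameters are not recoverable from text, so the default desk-scale
architecture is 4 blocks of 3³ kernels (padding 1) with 8/16/32/64 filters
and 2³/stride-2 pooling — fully configurable, and the full-scale input is
supported but not exercised by tests (a CPU-scale choice documented here as
the package's own).

Pre-training labels follow the CGI rule (healthy/relative with CGI = 0 →
0; patient groups with CGI *strictly* > 3 → 1; anything else excluded with
a logged count). Oversampling duplicates minority records within (sex,
age-decile) strata drawn in proportion to the majority's stratum
composition until classes balance, falling back to the nearest age bin when
a stratum is empty; the majority is never touched. Balancing happens before
any train/validation split — the upstream protocol is ambiguous on the
order, and balancing first carries a known leakage caveat for the
pre-training error estimate (it does not affect the target-task
evaluation).

"Error not decreasing for 100 epochs" is interpreted with a relative
improvement floor of 1e-6 (strict float comparison is seed-fragile), and
"revert by 100 epochs" as restoring the checkpoint of the *first epoch of
the non-improving span* (stop epoch − patience + 1); a rolling ring buffer
of `patience` checkpoints makes this exact, and the per-epoch parameter
checksums in the training history let tests verify the restored state.
Freezing excludes the first $k$ convolution blocks from the Adam update
entirely, so their parameters are bit-identical after fine-tuning; the
decision layers are re-initialized from the configured seed.

## Attribution

For a linear model with independent features the Shapley value is exactly
$\phi_{ij} = w_j (x_{ij} - b_j)$; tests verify equality with brute-force
coalition enumeration up to $p = 10$ and local accuracy (rows sum to the
margin difference). Two aggregation choices were open and are made
explicitly: (1) ranking is by mean *absolute* attribution across subjects,
ties broken by canonical feature index; (2) attributions are computed on
each fold's test subjects against the training-fold feature means and
pooled over all 5 × 10 folds. A sparse L1 model attributes exactly zero to
features outside its support, so a top-K with K much larger than the
support would be padded by zero-score ties in canonical order — the
pipeline therefore drops zero-score features from the regional ranking
(`top_k_voxels(..., drop_zero = TRUE)`), while the plain contract (padding
allowed) remains the default for the function itself.

## Problem sizes

Tests and the acceptance script run at desk scale as a deliberate design
choice: 8 mm or 6 mm grids for unit tests, the default 4 mm grid with 60
subjects for the planted-signal recovery run, 50 label permutations for the
chance-calibration run, and blob volumes of 8³ for CNN training checks.

## What passing tests do and do not show

The generator produces linear-Gaussian signals with exactly the coupling
structure the pipeline looks for. Passing recovery tests therefore shows
the *machinery* is correct — censoring rules fire as specified, regression
removes what it should, correlations and penalized fits are computed
correctly, attribution lands on the planted regions. It does not show that
real hallucination-related connectivity is this clean: real BOLD has
non-Gaussian artifacts, spatial autocorrelation beyond region boundaries,
scanner and protocol heterogeneity, and effect sizes far below
$\Delta\rho = 0.4$. The published headline accuracies live on 34 real
patients and are deliberately not targets of the synthetic runs. Known
limitations: no structural preprocessing (data are generated in reference
space), no slice-timing structure, no scanner physics, independent clinical
covariates, and a CNN that is intentionally small.
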