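---
title: "Methods: biospeckle activity and two-channel injury recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biospeckle activity and two-channel injury recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speckinj)
```

## The problem

Skinning injury removes the suberized phellem layer of a potato tuber.
Immediately after wounding, the exposed tissue is wet, bright and
metabolically hyperactive; over the following days a suberized closing
layer forms, the wound darkens, and activity falls back toward baseline.
The two imaging channels in this package see opposite ends of that time
course: laser biospeckle is most discriminative while the wound is fresh
and active, visible colour once the wound has darkened. This vignette
documents the models, the numerical choices, and what the synthetic data
do and do not establish.

## Biospeckle activity

A biospeckle acquisition is a stack of T monochrome frames recorded at a
fixed frame rate (12.5 Hz is the package default, with 512-frame
recordings the nominal full length). The analysis chain is:

1. **THSP.** One spatial column is extracted from every frame and the
   columns are placed side by side in chronological order, giving an
   H × T matrix whose rows are pixels and columns are time. The tracked
   column defaults to mid-width (`floor((W-1)/2)`, 0-based), which for a
   512-wide region is index 255 — the 256th column in 1-based counting.
   The convention is 0-based throughout the package to keep this
   off-by-one explicit.
2. **Co-occurrence matrix.** `COM = [N_ij]` counts how often intensity i
   at time t is followed immediately by intensity j at time t + 1. Every
   one of the H rows contributes its T − 1 temporal transitions, so
   `Σ N_ij = H (T − 1)`. Aggregating over all rows is a deliberate
   choice: it is the standard THSP construction and the only reading
   that uses the whole matrix.
3. **Normalization.** Each row is divided by the number of times its
   first gray level occurred: `M_ij = N_ij / Σ_j N_ij`. Rows of gray
   levels that never occur are left at zero rather than NaN — the
   normalization is undefined there and zero rows contribute nothing to
   the moment, which preserves the meaning of the statistic.
4. **Inertia moment.** `BA = IM = Σ_ij M_ij (i − j)²`. Diagonal entries
   (unchanged intensity) contribute nothing; distant transitions are
   weighted by the squared gray-level distance. A static stack gives
   exactly BA = 0.

Gray levels default to G = 256 (8-bit sensors; higher bit depths are
rejected in this version). G is configurable downward as an efficiency
knob.

### Prefix windows

Shorter time spans are analysed as *prefixes* of the recording:
`floor(window_seconds × frame_rate)` frames. At 12.5 Hz a 10 s window is
exactly 125 frames. A nominal 40 s window is 500 frames, although the
full recordings are 512 frames wide — 512 frames at 12.5 Hz is 40.96 s,
an inconsistency the acquisition convention never reconciles. Both
behaviours are reachable: numeric windows apply the floor rule, the
window `"all"` uses every frame. Pearson correlation (the default of the
usual statistics packages, and consistent with exact self-correlation 1
in reference tables) measures agreement between windowed and full-length
BA across specimens.

## The speckle simulator

There is no deposited instrument data, so the generator must create
stacks whose *temporal decorrelation* is controllable and physically
interpretable:

* Each frame is the squared modulus of a complex circular-Gaussian
  field — the standard model of fully developed speckle, whose intensity
  is negative-exponential (coefficient of variation 1, which the tests
  check on the raw, pre-quantization intensities).
* The field (not the intensity) evolves as an AR(1) process with
  coefficient `rho`: `E_t = rho E_{t-1} + sqrt(1 − rho²) W_t`. This
  guarantees the two limits exactly — `rho = 1` is a static stack
  (BA = 0 after quantization) and `rho = 0` gives independent frames —
  and makes `rho` a clean knob for activity: lower `rho`, higher BA.
* Spatial structure comes from Gaussian-smoothing the complex field
  (`grain_sigma`, default 1 px) — smoothing the amplitude keeps the
  field Gaussian, hence the intensity statistics intact.
* The stack is linearly rescaled to `[0, bit_depth − 1]` **per stack**,
  not per frame: per-frame rescaling would inject artificial
  frame-to-frame transitions and bias the inertia moment.

Default dimensions mirror the acquisition convention (512 × 512 × 512 at
12.5 Hz). The test suite and acceptance script run 64 × 64 × 125 stacks
(and 512-frame stacks where the windowing itself is under test): the
statistic is column-local, so narrower frames only reduce averaging, and
these sizes keep the full suite under a minute while leaving the
monotone BA–rho relationship (Spearman −1 over the grid 0.3…0.99, 20
seeds) and the 10 s-vs-full correlation (>0.98) comfortably detectable.
Sound and injured classes are emulated with `rho = 0.95` and
`rho = 0.5`: under the per-stack AR(1) model these produce roughly an
order-of-magnitude BA separation, qualitatively matching the reported
activity jump in freshly injured tissue. Camera noise beyond
quantization, polarization and light-tissue interaction are out of
scope.

## Visible features

Patches are 65 × 65-pixel ROIs. Gray conversion is ITU-R BT.601
luminance (0.299 R + 0.587 G + 0.114 B) — the conversion is a
convention, fixed and documented rather than configurable.

* **Colour (6):** per-channel means and population SDs.
* **GLCM (8):** gray quantized to 32 levels; symmetric co-occurrence
  matrices at distance 1 in directions 0°/45°/90°/135°; ASM, entropy,
  inertia and correlation, each summarised by its mean and SD across the
  four directions. Aggregating over the direction axis is what makes the
  printed count of 8 come out (4 statistics × mean/SD); the correlation
  of a zero-variance patch is defined as 0. The 32-level quantization is
  an efficiency default, config-exposed.
* **Gabor (108):** 12 complex filters (wavelengths 4/8/16 px spanning
  the 65-px ROI, orientations 0°/45°/90°/135°, 1-octave bandwidth,
  aspect ratio 0.5), applied by FFT convolution with replicate borders;
  the ROI is split into a 3 × 3 block grid and the mean response
  magnitude per (filter, block) is one feature. Mean magnitude (rather
  than energy) is the fixed block statistic; either satisfies the
  12 × 9 = 108 count.
* **DT-CWT (12):** one-level dual-tree complex wavelet decomposition
  into six oriented subbands (≈ ±15°, ±45°, ±75°); per subband the mean
  |real| and mean |imag| give 6 × 2 = 12 features. The dual-tree
  structure is implemented directly (odd-length biorthogonal LeGall 5/3
  analysis pair, symmetric extension, quad-to-complex combination of
  the three highpass images); one level suits 65-px ROIs, and odd sizes
  are padded symmetrically by one pixel. Highpass filters sum to zero,
  so all 12 features vanish on constant patches.

The signed contrast `Con = mean_gray(SS) − mean_gray(IS)` is positive
once the wound has darkened (≈ +31 after one day in the tabulated
regimes) and negative in the first hour (≈ −13), when the wet wound
reflects more light.

The patch generator draws Gaussian channel noise (SD 8 by default —
visibly grainy but far from saturating 8 bits) around a matte skin tone,
optionally stamps darkened disks emulating lenticel spots into the
injured patch, and then shifts the injured patch so the *realized*
contrast matches the request exactly up to 8-bit rounding. Texture
realism is deliberately minimal: no quantitative texture description of
injured skin is available to emulate, so passing texture-feature tests
demonstrates contract correctness (lengths, invariances, oracle
agreement), not field performance.

## Classifiers

* **LS-SVM.** The least-squares SVM is trained by solving its defining
  KKT linear system exactly (labels ±1, RBF kernel
  `exp(−‖x−z‖²/(2σ²))`, ridge `1/γ` on the diagonal), rather than by
  calling a generic SVM: the solver is a dozen lines and exactly
  testable — every fit records its relative KKT residual, bounded at
  1e−8 in the tests (observed ~1e−16). Features are z-scored with
  training-set statistics only, to avoid leakage.
* **Binary logistic regression.** IRLS with step-halving, so the
  log-likelihood is non-decreasing across iterations by construction
  (the trace is kept on the model). Complete separation — routine for a
  scalar feature that separates the classes — is detected when
  standardized coefficients pass a cap (default 30), flagged, and the
  coefficients capped; predictions remain correct. The fit matches
  `glm(family = binomial)` to 1e−6 on non-separated data, which the
  tests use as an independent cross-check.
* **Evaluation.** The split protocol is a stratified random 2:1
  train/prediction split, repeated (default 50 times) with per-repeat
  seeds derived from one master seed; mean accuracy, SD and pooled
  confusion tallies are reported. Repetition is the package's choice
  where the original protocol is underdetermined: it stabilises the
  mean and sidesteps the unreconcilable per-group test-set sizes.
  Hyperparameters come from `tune_lssvm()`, a deterministic
  cross-validated grid search (ties break to the smallest γ, then
  smallest σ).

## Statistics utilities

Pearson correlation with its t-distribution p-value, one-way ANOVA
(with the two-group F = t² identity tested to 1e−12), mean ± SD group
summaries (sample SD; single-value groups report 0 with a flag), and
pairwise Welch tests with Bonferroni correction in place of letter-style
post-hoc groupings, whose original procedure is unnamed.

## Pipeline and I/O

`pipeline_config()` validates a single configuration (unknown keys
rejected, incompatible settings — e.g. an ROI too small for the wavelet
family — fail before any compute) and `run_pipeline()` executes
simulate → features/BA → classify → stats into a run directory with a
config snapshot, a timed log and CSV/JSON outputs; identical
config + seed reproduces the result files byte for byte. Speckle stacks
are read and written as multi-page 8-bit TIFF (or lexicographically
ordered frame directories, zero-padded names required), patches as PNG,
with sidecar JSON for simulation parameters. Only 8-bit imagery is
accepted in this version.

## Known limitations

* The AR(1) speckle model captures temporal decorrelation, not the
  spatial heterogeneity, drift or external vibration of real
  acquisitions; accuracies on synthetic classes say nothing quantitative
  about field accuracy on tubers.
* Synthetic injured patches differ from sound ones in mean level and
  lenticel spots only; texture families are validated by contract, not
  by realism.
* Gabor wavelengths, GLCM quantization and the DT-CWT level are
  conventions chosen here (and config-exposed); other choices satisfy
  the same feature-count contracts.
* No automatic injury segmentation: ROIs are supplied by the caller.
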