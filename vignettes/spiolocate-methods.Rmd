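---
title: "Localizing SPIO-labeled cells in multi-echo gradient-echo MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing SPIO-labeled cells in multi-echo gradient-echo MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spiolocate)
```

## The problem

Cells labeled with superparamagnetic iron oxide (SPIO) nanoparticles can be
followed non-invasively with MRI: the particles accelerate proton spin
dephasing, shortening T2\* and imprinting a characteristic dipole pattern on
the image phase. Detecting *where* labeled cells sit — and *how many* — from a
multi-echo gradient-echo acquisition is hard at low cell densities, because a
voxel with a handful of labeled cells looks, in any single feature, much like
a voxel of dark background, partial-volume boundary, or low proton density.

`spiolocate` treats the task as voxel-wise supervised classification over a
multiparametric feature space: magnitude- and phase-derived feature volumes
are extracted from a baseline (pre-contrast) and a contrast scan, every voxel
inside the object is described by a 13-dimensional feature vector, and an
RBF-kernel C-support-vector classifier (C-SVC) decides *containing* versus
*not containing* labeled cells. R2\* relaxometry then converts positive voxels
to iron oxide concentration via a phantom-derived linear calibration.

Because the original study was performed on physical agarose phantoms and
rats, the package ships a physics-based simulator that reproduces the phantom
study end to end, with exact ground truth. Everything the analysis side
consumes — NIfTI volumes with a YAML manifest — can equally come from a real
scanner.

## Forward model of the simulator

For tissue with proton density $\rho_0$, background rate $R_2^{*,bg}$ and
iron oxide concentration $c$ (µM Fe₂O₃), the complex signal at echo time
$TE$ is

$$ S(TE) = \rho_0\, e^{-(R_2^{*,bg} + r \cdot c)\,TE}\,
   e^{i(\phi_0 + 2\pi f_0 TE + \phi_{dip}(TE))} + \varepsilon, $$

with relaxivity $r$ (1/s per µM), a constant receiver phase $\phi_0$, a smooth
off-resonance ramp $f_0$ of a few Hz across the field of view, and complex
Gaussian noise $\varepsilon$ of standard deviation $\sigma$ per channel, so
the stored magnitude is Rician. The susceptibility-induced phase
$\phi_{dip}$ is the concentration map scaled to a susceptibility map
($\chi = k_\chi c$, ppm) and convolved with the unit dipole kernel in the
Fourier domain,

$$ D(\mathbf k) = \tfrac13 - \frac{k_z^2}{|\mathbf k|^2}, \qquad D(0) = 0, $$

times $\gamma B_0 TE$. The kernel's $k=0$ term is zeroed (no bulk shift), so
the simulated field has exactly zero spatial mean and is linear in both $c$
and $TE$ — two properties the test suite asserts to $10^{-10}$. A practical
note: the *discrete* inverse FFT of $D$ matches the continuum dipole
$(3\cos^2\theta - 1)/(4\pi r^3)$ closely at oblique lags but deviates on the
exact grid axes; this is a sampling property shared by standard
implementations of the kernel, and the tests therefore probe oblique
directions (and the $-2$ axis/equator ratio, which survives because both
probes carry the same axis factor).

### Default phantom geometry and study conditions

The default `paper_block_spec()` is an agarose block with five cylindrical
inlays in a 2:1 dilution series of labeled cells: 480, 240, 120, 60, 30
cells/mm³, corresponding to 313, 156, 78, 38, 19 µM Fe₂O₃ by the dilution
look-up table (`cells_to_concentration()`; the analytic conversion from 90 pg
iron per cell is provided but does not exactly reproduce the table, so the
table is authoritative). The acquisition protocol is a 3D FLASH-type
multi-echo scheme with TE = 2.54, 3.78, 11.34 ms, TR = 200 ms, flip 25°,
4.7 T, 0.4 mm isotropic voxels. The grid is 64 × 128 × 32 — the block and
inlays are scaled relative to the original physical phantom (block
22.4 × 48 × 10.4 mm, inlays Ø8 × 6.4 mm) so a single simulated study stays at
about a quarter million voxels; the dilution series, voxel size, protocol and
geometry *type* are preserved. Partial-volume voxels belong to an inlay when
at least 50% of a 3×3×3 subgrid of the voxel falls inside the cylinder.

Two constants calibrate contrast strength, and were fixed once as the
package's study conditions:

* **relaxivity** $r = 0.6$ s⁻¹/µM — the 19 µM inlay then sits at roughly one
  standard deviation of the voxel-wise R2\*-fit noise at the default 5% noise
  level (hardest inlay, detectable but weakest), while at 313 µM the signal
  at the longest echo falls below the magnitude noise floor, so the R2\* fit
  drops that echo and flags the voxel — the mechanism behind underestimation
  of the highest concentration;
* **susceptibility** $k_\chi = 0.006$ ppm/µM — the strongest inlay imprints a
  multi-radian phase perturbation at the longest echo (wraps present, some
  spatial aliasing at inlay faces, as in real data) while the weakest stays
  near the phase-noise floor.

Noise defaults to $\sigma = 5\%$ of the background proton density, seeded;
baseline and contrast scans use independently derived seeds. The in-vivo-like
variant (`build_invivo_like_spec()`) adds low-proton-density confounder
regions (air/bone analogs) with elevated apparent R2\* but no dipole
signature — the configuration that defeats single-feature detection and
motivates the multiparametric classifier.

## Feature extraction

**Magnitude.** Per-echo signal intensity ρ; the volume of interest (VOI) from
two-class spatial fuzzy c-means on (intensity, 3×3×3-neighborhood-mean)
channels of the first echo, membership-thresholded at 0.5, then
largest-component selection and hole filling so signal voids inside the
object stay in the VOI; per-echo |Δρ| against the registered baseline; and
the R2\* map from a weighted log-linear least-squares fit of
$S(TE) = S_0 e^{-R_2^* TE}$ with weights $S^2$. Echoes at or below the noise
floor (default 2× the median air magnitude) are excluded; voxels left with
fewer than two usable echoes fall back to the first two echoes and are
flagged, as are voxels with any excluded echo or a clamped negative rate.
With three echoes a nonlinear fit adds conditioning problems without
information, so the log-linear form is used throughout.

**Phase.** The wrapped phase is unwrapped per echo with a best-pair-first
region-merging algorithm: every in-mask voxel starts as its own region,
edges between 6-neighbors are scored by mean boundary magnitude, and regions
merge best-edge-first (union–find with per-region 2π potentials), adding the
2π multiple that minimizes the step across the merging edge. The result is
congruent to the input modulo 2π; on fields whose true adjacent-voxel steps
stay below π the reconstruction is exact up to one global 2π constant.
Unreliable voxels are found by fitting each voxel's phase against TE and
extrapolating to the excitation pulse: a voxel is unreliable when the RMS
residual exceeds 0.15 rad or the TE→0 intercept deviates more than 0.25 rad
from a 5-voxel-box-smoothed intercept field. These tolerances were set from
a Monte-Carlo requirement — a voxel with independent uniform phases must be
flagged with probability above 0.99 while exactly linear voxels with ~0.07 rad
phase noise are false-flagged at under 0.1%.

The short-range-perturbation map **s** is a frequency-domain band-pass of the
unwrapped phase of the second echo (the best compromise between accumulated
phase and noise), with raised-cosine shoulders around a pass band of spatial
periods 2–10 voxels; values outside the VOI are filled by inward
nearest-neighbor diffusion before the FFT so the filter sees no artificial
edge. The filter passes in-band content with unit gain (reapplication changes
it by well under 1% RMS) and suppresses long-wave content such as the
background off-resonance ramp; content in the raised-cosine transition
shells is, by construction of any tapered filter, attenuated partially.
Perturbation sources are localized by thresholding |s|, 26-connected
labeling, merging components whose 2-voxel dilations overlap (the two lobes
of one dipole), and taking strength-weighted centroids. The propagation map
**p** fits |s(TE)| per voxel by a line through the origin over the echoes of
the baseline-subtracted phase — perturbations spread faster around stronger
susceptibility sources, and the origin constraint reflects that the
perturbation vanishes at TE = 0.

## Baseline alignment

The baseline magnitude (first echo) is registered to the contrast magnitude —
baseline always moves, so the contrast data containing the labeled cells are
never interpolated. The similarity is normalized mutual information,
$NMI = (H(A)+H(B))/H(A,B)$, from a 32-bin joint histogram with hard bin
assignment; $NMI(a,a) = 2$ exactly, and smoothness of the objective in the
transform parameters comes from trilinear resampling of the moving image.
Three implementation details matter far more than optimizer choice here, and
each was adopted after the naive variant measurably failed:

1. both images are evaluated on a half-voxel-offset grid, so *every*
   candidate transform — identity and integer-voxel shifts included — incurs
   the same interpolation blur; otherwise interpolation-free grid-aligned
   shifts carry spuriously sharp histograms and trap the search voxels away
   from the optimum;
2. both images are box-smoothed (half-width 2) before histogramming, removing
   noise-induced micro-maxima of the NMI landscape;
3. the search runs at half resolution (cyclic direction-set line sweeps over
   translations and in-plane rotation for capture, ±2.4 mm, then Nelder–Mead
   over all six parameters), and full resolution only polishes.

On the default phantom this recovers injected transforms to well under 0.01
voxel and 0.01°. Non-rigid refinement (diffusion-regularized demons on the
rigid-aligned magnitude, displacement capped per iteration and smoothed each
step so the Jacobian stays positive) is available but off by default: the
simulated pairs are rigidly related, and the phantom acceptance runs are kept
deterministic and fast. Transforms are applied to the phase data through the
complex representation — magnitude and phase are rebuilt into re/im,
interpolated, and re-extracted — because interpolating wrapped phase across a
branch cut is meaningless.

## Classification

The feature stack holds 13 channels per voxel — 3×ρ, 3×|Δρ|, R2\*, 3×
baseline-subtracted unwrapped φ, the unreliable-φ indicator, s, and p — each
standardized over the VOI by median/MAD (scale 1 where the MAD vanishes, as
for the binary indicator). Unreliable voxels keep a decision: their
phase-derived channels are imputed to the standardized center and the
indicator carries the information that they were unreliable.

Training samples a seeded uniform 15% of VOI voxels, labeled from the phantom
ground truth (a stratified mode preserving the class ratio is available).
The C-SVC uses $k(x_i, x_j) = \exp(-\gamma \lVert x_i - x_j \rVert^2)$ with
inverse-class-frequency weights (about 14% of VOI voxels are positive in the
default phantom). $(C, \gamma)$ are selected by five-fold stratified
cross-validation over the grid $C \in \{2^{-3}, 2^{-1}, \ldots, 2^9\}$,
$\gamma \in \{2^{-9}, \ldots, 2^3\}$, maximizing *balanced* accuracy — the
mean of per-class accuracies, the selection metric consistent with the
class-weighted loss; raw accuracy is nearly flat across the grid at this
imbalance and degenerates the choice. Because libsvm training is quadratic in
sample count, the grid search runs on a seeded stratified subsample (default
4000 rows) of the training set and the winning point is refit on the full
training set. Ties break toward smaller γ, then smaller C (smoother
boundary). The trained model, its scalers and the CV table travel together,
so a model trained on one phantom applies unchanged to later scans.

## Concentration estimation and evaluation

A linear calibration $R_2^* = a + b\,c$ is fit through (concentration,
median inlay R2\*) points of the training phantom plus a background point at
$c = 0$ (medians resist partial-volume edge voxels; the background sample
excludes a 2-voxel dilation of the inlays). Positive voxels get
$c = \max(0, (R_2^* - a)/b)$; everything else is exactly 0.

Evaluation mirrors the phantom-study conventions: per inlay, sensitivity
TP/(TP+FN) and specificity TN/(TN+FP) are computed inside an evaluation
region consisting of the inlay plus a 3-voxel background shell (the per-inlay
negative set is otherwise undefined); detected/real volume ratios attribute
each predicted-positive voxel to its nearest inlay within 3 voxels; the halo
fraction is the share of false positives within a 2-voxel shell of the truth;
and a global specificity over the whole VOI is reported alongside.

## What the simulation does and does not show

Passing the phantom suite demonstrates that the pipeline recovers the study's
qualitative and quantitative structure under the stated forward model:
sensitivity rising with concentration and the lowest inlay hardest, mean
specificity ≥ 0.95 in the inlay regions, training-phantom volume recovery
near 1, concentration accurate to ~10% with the highest concentration limited
by the noise floor at the longest echo. It does not demonstrate robustness to
effects the simulator deliberately omits: flip-angle/TR dependence, B0
inhomogeneity beyond the inclusion dipoles, k-space sampling artifacts,
motion, particle degradation over days, or scanner-specific phase
reconstruction quirks. The in-vivo-like variant probes exactly one real-data
failure mode — low-proton-density tissue mimicking iron in magnitude features
— and shows the phase features resolve it; real anatomy is richer than that.

## Problem sizes and determinism

The default acceptance-style run — two 64×128×32 phantoms, full feature
extraction, grid search, final training on ~26k samples and prediction over
~350k VOI voxels — takes a few minutes on one CPU; the unit-test fixtures use
32×48×16 grids with three inlays and a reduced hyperparameter grid. All
stochastic stages (noise, sampling, folds) draw from locally scoped RNG
streams derived from the configured seed, so identical configurations
reproduce results bit for bit, which the suite asserts.
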