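---
title: "Cross-modal spatial analysis of brain maps: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal spatial analysis of brain maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmodal)
```

## The problem

Hyperpolarized [1-¹³C]pyruvate MRI yields coarse (≈15 mm) brain maps of
pyruvate delivery and of its enzymatic products lactate and bicarbonate.
Metabolic PET yields maps of glucose consumption (CMRglc), blood flow (CBF),
oxygen consumption (CMRO₂) and blood volume (CBV). Asking "which PET
quantity does each ¹³C signal spatially resemble?" is a statistics problem
with two traps: global intensity scales differ arbitrarily between subjects
and modalities, and brain maps are spatially autocorrelated, so naive
voxelwise p-values are wildly anti-conservative. `crossmodal` implements the
standard remedies — whole-brain-mean normalization, residual (rather than
ratio) maps, parcel-level inference with a spin permutation null, FDR
control, and a symmetric two-block PLS — as reusable, tested components.

## Pipeline model

**Sum images.** Dynamic series are integrated by frame summation. Supported
windows: every frame (the 12-frame, 5 s-spacing HP acquisition), a half-open
fixed window `[start, start + duration)` (e.g., 60 s from uptake start for
O₂ and H₂O), and the scan tail in minutes (last 20 min for FDG). Frame
summation, not trapezoidal integration, is used deliberately: with uniform
frame spacing the two differ by a constant factor that the subsequent
normalization removes. Uptake start is detected as the first frame whose
within-mask mean exceeds the first frame's mean by more than 5% of the
dynamic range — the margin makes "first increase" robust to frame noise; a
series with no increase is an error, not a silent default.

**Normalization.** Each sum image is divided by its within-mask mean, so the
whole brain has mean exactly 1. This removes subject-level multiplicative
effects (polarization, dose) and makes every downstream statement
local-to-global. Normalization is idempotent and scale-invariant, and those
contracts are tested to 1e-10.

**Residual maps.** GI, LBR, LPR and BPR are residuals of voxelwise OLS (with
intercept) across within-mask voxels. Residuals are preferred to ratios
because they need no guard against near-zero denominators. Each residual map
has within-mask mean 0 and is exactly orthogonal to its regressor. Residuals
are computed per subject and then group-medianed (matching per-participant
processing); residualizing the group medians instead is available via
`residuals_per_subject = FALSE`. Vascular artifact removal regresses CBV out
of CMRO₂ and **restores the fitted intercept** so the corrected map stays
positive for ratio use — the plain mean-0 residual is available with
`restore_intercept = FALSE`. OEF divides the corrected O₂ image by the H₂O
image; voxels whose denominator falls below 5% of the within-mask median are
excluded from the mask rather than clamped, because a handful of near-zero
divisions would otherwise dominate the map.

**Group aggregation and smoothing.** Group maps are voxelwise medians (even
counts average the central pair — the convention matters only for even
cohorts). The finer modality's group maps are smoothed with an isotropic
Gaussian kernel, σ_vox = FWHM/(2√(2 ln 2))/voxel size, default FWHM 14 mm.
Smoothing is *mask-renormalized*: `smooth(map·mask)/smooth(mask)` within the
mask. Plain convolution attenuates values near the mask edge by averaging in
outside-mask zeros; renormalization removes that bias and preserves
constants exactly (tested against a brute-force triple-loop convolution).
`optimize_fwhm()` reproduces the empirical kernel choice: it scans a
candidate grid and keeps the width maximizing the mean voxelwise Spearman
correlation across paired maps, breaking ties toward the smaller width
(least information loss).

**Parcel inference.** Correlations are Spearman's ρ (Pearson on average
ranks; ties get mean ranks). Voxelwise ρ is reported descriptively only.
Inference uses 200 parcel medians and a spin test: each of `n_perm`
(default 10,000) Haar-uniform rotations — drawn by QR-orthonormalizing a
Gaussian matrix with determinant correction — rotates the parcel centroids
on the unit sphere, each parcel takes the value of the nearest original
centroid (max dot product), and the rotated map is correlated with the
unrotated partner. The reassignment is a surjection (values may duplicate),
matching the standard spin-test family on uneven parcel geometry. The
p-value is two-sided with the add-one correction, so its floor is
1/(n_perm+1). Two-sidedness is a package choice: both signs of association
are interpreted downstream, and the sidedness was otherwise unspecified.
FDR uses Benjamini–Hochberg step-up at α = 0.05, one family per comparison
matrix. A mirrored two-hemisphere rotation mode (standard for bilateral
atlases) is a known extension point, not implemented; the synthetic world
uses a single sphere.

**Two-block PLS.** `fit_pls()` standardizes the columns of both
voxel × channel blocks (matching the canonical-mode implementation the
workflow targets, which scales to unit variance) and runs NIPALS: alternate
`w ∝ Xᵀu`, `t = Xw`, `c ∝ Yᵀt`, `u = Yc` to convergence (tol 1e-6 on the
weight update, max 500 iterations), then deflate *both* blocks by their own
scores — canonical mode, symmetric in the blocks, unlike regression-mode
PLS. Component-1 weights equal the leading singular vectors of the
standardized cross-covariance XᵀY, which the tests use as an independent
oracle. PLS signs are arbitrary, so each component is flipped to make its
largest-magnitude X weight positive (the Y weight flips jointly). Score
maps are normalized to an absolute maximum of 1 for display; Spearman score
correlations are unaffected.

## The synthetic world

The generator exists so that every stage can be tested against known ground
truth. It emulates:

* **Geometry** — a 32³ grid at 6 mm (desk-scale, comparably coarse to the
  real HP data); the "brain" is a centred ellipsoid covering ≈40% of voxels,
  and the "cortex" is its outer 30% radial band, which maps cleanly onto the
  unit sphere for the spin test. No real anatomy is implied.
* **Latent structure** — `n_latents` Gaussian random fields, white noise
  smoothed to 15 mm FWHM (the native HP resolution) and z-scored within the
  mask. Channels are linear mixes of the latents: by default a metabolic
  latent loads lactate/bicarbonate and CMRglc/CBF/CMRO₂, a vascular latent
  loads pyruvate and CBV — the qualitative pattern the real analysis
  reports — plus a weak nuisance latent.
* **Nuisance** — mixed maps are shifted so the within-mask minimum is 0.1×
  the range (ratios and lognormal gains need positivity), multiplied by a
  per-subject, per-channel lognormal gain (sd 0.2 on the log scale — the
  polarization/dose analog that normalization is supposed to remove
  exactly), and perturbed with additive voxel noise at 5% of each map's SD
  (clamped at zero to keep frames nonnegative). The study reports no
  quantitative subject-level variance, so these two noise levels are chosen
  once as plausible, not calibrated.
* **Dynamics** — 12 frames at 5 s; gamma-shaped boluses peaking early for
  pyruvate and later for lactate/bicarbonate, a rise-to-plateau for PET
  channels. Weights sum to 1 per channel, so the all-frame sum image equals
  the static map exactly in the noiseless case.
* **Parcellation** — 200 centroids from a (seed-rotated) Fibonacci lattice;
  shell voxels are radially projected to the sphere and labeled by nearest
  centroid. If a rotation leaves an empty parcel on the discrete grid,
  further seed-derived rotations are tried deterministically.

What a green test does **not** establish: realistic pharmacokinetics,
scanner noise, registration error, anatomical parcel shapes, or
between-modality resolution mismatch beyond a single smoothing scale. The
synthetic latent space is low-rank, so derived maps can correlate with raw
channels more strongly than real data would (e.g., GI inherits the vascular
latent almost exactly); tests on planted-structure recovery therefore rank
raw channels only.

## Numerical choices

* Gaussian kernels are truncated at 4σ and applied as dense separable
  matrix products; the brute-force oracle in the tests uses the same
  truncation.
* OLS uses the closed form on centred data — one pass, no QR needed for a
  single regressor.
* The spin test re-ranks the rotated vector at every permutation because
  nearest-centroid reassignment can duplicate values and change tie
  structure.
* `spearman_rho` refuses zero-variance input instead of returning `NA`.
* Seeds: every stochastic entry point takes an explicit seed, runs under it,
  and restores the caller's RNG state afterwards. The pipeline derives
  subject seeds as `seed·1000 + subject`.
* NIfTI-1 I/O is implemented in-package (float32/float64 write; uint8,
  int16, int32, float32, float64 read; gzip supported; slope/intercept
  applied on read) because no R NIfTI reader is assumed present. It was
  validated against nibabel round-trips during development.

## Calibration evidence

The acceptance suite checks, at fixed seeds: normalization mean exactly 1;
residual mean 0 and orthogonality at 1e-8 with a hand-computed 3-voxel OLS;
NIPALS weights vs the SVD oracle at 1e-6 and score-map maxima exactly 1;
spin-test rejection rate on 500 independent smooth map pairs within
[0.03, 0.07] at α = 0.05 (measured 0.048 in development); and end-to-end
recovery of the planted vascular/metabolic split in both the correlation
matrix and the PLS weights.

## Known limitations

Single-sphere spin rotations (no hemisphere mirroring); no registration, so
all inputs must already share a grid; no kinetic modelling — sum images
only; parcel centroids are taken as given (or synthesized), never derived
from a surface mesh; absolute quantification is out of scope since every
map is whole-brain normalized.
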