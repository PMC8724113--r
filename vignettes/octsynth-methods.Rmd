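---
title: "Generating labeled synthetic OCT with point distribution models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating labeled synthetic OCT with point distribution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octsynth)
```

## The problem and the model

Segmentation networks for retinal OCT need training volumes whose layer
boundaries are known voxel-by-voxel. `octsynth` produces such data by
*generating the labels first*: a statistical shape model is trained on the
boundary surfaces of a small labeled cohort, new plausible boundary
configurations are sampled from it, and the image is rendered from the
sampled geometry. The label is therefore exact by construction rather than
the output of a segmentation step.

The shape model is the classic point distribution model. Nine boundary
surfaces per volume (inner limiting membrane down to Bruch's membrane) are
subsampled to 51 landmarks per boundary per B-scan — the first and last on
the image edges, the middle landmark anchored to the foveal column, and the
remaining points spaced evenly *within each half*. Fovea anchoring is what
establishes correspondence across eyes: landmark 26 always sits on the pit.
With a 19-B-scan raster this yields 969 landmarks per surface and 8 721 per
volume, each contributing its (x, y, z) voxel coordinates to the shape
vector. After generalized Procrustes alignment (rotation, isotropic scale,
translation), the mean shape and the eigenpairs of the covariance

$$S = \frac1N \sum_{i=1}^N (\bar x - x_i)(\bar x - x_i)^\top$$

define the linear generative model $X \approx \bar x + P b$. Coefficients
are assumed independent Gaussians with the training variances; healthy-mode
sampling restricts each $b_i$ to $\pm 3\sqrt{\sigma_i}$, which keeps
geometries inside the span the cohort supports. Note the $1/N$
normalization: it is retained exactly as the model is defined, not replaced
by $1/(N-1)$, so frozen test values are reproducible against the formula as
written.

Three readings and conventions deserve a note:

* **Mode count.** The retention rule is read as a *cumulative* explained
  variance threshold (default 0.94): keep the smallest $t$ whose cumulative
  eigenvalue share reaches the threshold. A per-component reading
  ("each component above 94 %") would almost always keep a single mode,
  which contradicts the multi-mode models the method is meant to use. The
  threshold is exposed as `variance_fraction`.
* **Constraint handling.** Random draws use per-component *rejection*, so
  the constrained distribution is a truncated Gaussian; explicit
  user-supplied coefficients are *clipped* (with a warning), so a
  deliberate request for an extreme shape behaves deterministically.
* **Degenerate cohorts.** Identical training shapes produce a zero-variance
  model with one conventional mode; a single-reference DME library is
  accepted as that degenerate case so the one-reference synthesis path
  works.

Mode signs are fixed (first non-negligible component positive), eigenvalue
ties resolve by the stable ordering of the SVD, and the PDM is computed via
the SVD of the centred data matrix — equivalent to the covariance
eigendecomposition (the tests verify this against an explicitly assembled
$S$) but cheap when the coordinate count far exceeds the cohort size.

### Alignment frame

Generalized Procrustes iterates similarity fits against the running mean
(tolerance $10^{-8}$, at most 50 iterations), with the mean renormalized to
its initial centroid size to avoid the well-known shrinkage of
scale-inclusive GPA. The GPA optimum is unique only up to one global
similarity; the output frame is pinned by composing all transforms with the
inverse of the first shape's transform. This makes three properties exact
rather than approximate: identical inputs give identity transforms, the
first shape is never moved, and re-aligning an aligned set is a no-op.

## Rendering

A sampled shape vector is turned back into dense surfaces by a monotone
cubic spline (Fritsch–Carlson) through each curve's 51 landmarks, clamped
to the axial range, followed by a cumulative-max projection from the top
surface down. The projection enforces the non-crossing invariant
$z_1 \le \dots \le z_K$ that every surface set in the package must satisfy;
for constrained samples it is virtually always a no-op, but it guarantees
the invariant in the unconstrained DME mode too.

Voxel ownership is half-open: row $r$ belongs to layer $k$ when
$z_k \le r < z_{k+1}$, so a voxel exactly on a boundary belongs to the
layer below it. Layer brightness is estimated from a random fraction
(default 0.5, re-drawn per synthetic volume to diversify appearance) of the
training B-scans as the pooled mean intensity between the bounding
surfaces. The choroid band and the vitreous background are copied per
A-scan from a reference volume, linearly resampled so the copied segment
exactly fills the target extent.

Speckle is modeled as signal-proportional multiplicative noise,
$I' = \mathrm{clip}(I(1+\eta), 0, 1)$ with $\eta \sim N(0, \sigma^2)$ per
voxel; a unit-mean gamma multiplier is available as an alternative family.
This is the standard surrogate for OCT speckle, not a coherent-scattering
simulation; $\sigma$ is deliberately a free parameter (typical range 0 to
0.2) because producing *many* noise levels is part of the use case
(denoising benchmarks, robustness sweeps). The level 0 returns the input
bit-for-bit.

### Vessels

Vessel appearance is its own 1-D PDM over multiplicative intensity
profiles across a fixed column window. Rendering normalizes the sampled
profile so its window-edge baseline is exactly 1 — applied
multiplicatively, the modulation then matches the local host brightness by
construction, which is how "normalize to the host region" is realized
here. Columns under a vessel are darkened from the vessel's depth (surface
4 by default) down through the outer layers and choroid by the profile
itself, and brightened above it by $1 + g(1 - p)$ with gain $g = 0.6$; the
reciprocal-dip form is a modeling choice, as no closed form is prescribed
for the bright inner shadow. Placements are *generated* (the package must
run data-free): track centres are drawn outside a configurable foveal
avascular zone with a minimum separation, persist across B-scans with
bounded lateral jitter, and can alternatively be read from a CSV when real
shadow positions are available.

## DME mode

The pathology pipeline is the 2-D version of the same model, with two
differences. First, sampling is *unconstrained*: edema pushes boundaries
beyond the healthy $3\sigma$ band, so the limit is eliminated. Second,
image content is not rendered from layer means but transferred column-wise
from the most similar reference B-scan, chosen by mean-centred SSD between
first boundaries (mean-centring removes axial placement; ties take the
lowest index). Per column and per inter-boundary band, the reference's
intensity profile is linearly resampled to the new band's thickness; the
fluid mask undergoes the *same* per-column axial map with nearest-neighbour
sampling so it stays binary and lands in the same layer it occupied in the
reference. Transfer from a single best reference (rather than a blend) is
an interpretational choice; it keeps fluid texture internally consistent.
Because fluid is only ever mapped band-to-band, every synthesized scene
keeps its fluid voxels between boundaries 1 and 8 — the constructor
verifies this invariant rather than silently fixing it.

## Evaluation battery

* **Thickness maps** difference two surfaces per (B-scan, column); maps
  are converted to micrometres when a voxel spacing is attached. The
  telescoping identity (total = sum of consecutive layers) holds exactly.
* **En-face projections** average intensity between two surfaces along
  depth; empty bands yield NA. Vessels show dark in outer-layer and bright
  in inner-layer projections, and the tests assert that inequality at
  every planted vessel.
* **GLCM features** quantize a region to `n_levels` equal-width bins
  (default 8) over its own range, count *ordered* pixel pairs at one
  offset (default right-neighbour), and evaluate energy, contrast,
  homogeneity and correlation exactly as the standard formulas print them.
  A constant region returns energy 1, contrast 0, homogeneity 1 and an NA
  correlation (undefined, not an error). Correctness is pinned to a
  brute-force double-loop oracle at $10^{-12}$.
* **Two-sample K-S** computes $D$ as the maximum ECDF gap over pooled
  points and the asymptotic Kolmogorov p-value; the series is evaluated in
  its alternating form for large arguments and its theta-dual form for
  small ones, so the p-value is accurate where the alternating series
  converges slowly. Matched empirical quantiles are returned for Q-Q
  plotting. `stats::ks.test` serves as an independent cross-check in the
  tests, not as the implementation.
* **Group comparison** mirrors the usual validation table: per layer
  (total macula 1–9, RNFL 1–2, GCIPL 2–3, RPE 8–9 by default — the
  name-to-surface mapping is configuration, since names alone do not fix
  indices), per-volume mean thickness, group mean ± SD and a two-sample
  p-value. Welch's t-test is the default because the underlying test
  behind such tables is typically unnamed; Wilcoxon is available. Texture
  features are compared per-image across groups (K-S over per-image
  feature values, the 10-vs-10 protocol), not over pooled pixels.

## The phantom generator

The phantom stands in for a segmented training cohort and is deliberately
parametric-analytic: each surface is a base depth plus a Gaussian foveal
pit (deep at the ILM, vanishing toward Bruch's membrane) plus a smooth
low-order polynomial perturbation, with per-volume axial shift, thickness
scale, pit-depth jitter and fovea position jitter providing population
variation. Closed forms mean exact oracles: the total-thickness map of a
jitter-free phantom equals its generating formula to $10^{-9}$, and PDM
coefficients sampled with known $b^\*$ are recovered below $10^{-6}$. The
default geometry is a 19 × 512 × 496 macular raster with five volumes, the
typical cohort such a generator is trained on. Ordering is enforced by
construction (the pit scales with the thickness scale so pit gradients
cannot outrun the inter-surface gaps) and verified; if perturbations still
cross, the amplitude is halved and the volume re-drawn, and generation
fails loudly after four halvings. DME references replace the pit by a
central bulge and carve 1–3 ellipsoidal hyporeflective pockets into the
mid-retinal layers, clipped strictly inside boundaries 1–8.

What the phantom does *not* emulate: real speckle statistics (spatially
correlated, non-Gaussian), realistic texture within layers beyond a smooth
lateral modulation, vessel tortuosity, motion artefacts, and pathology
other than fluid pockets. Passing tests therefore demonstrate the
correctness of the machinery — alignment, eigendecomposition, sampling
bounds, rendering conventions, transfer maps, statistics — on data whose
ground truth is known exactly; they do not certify photorealism on any
particular device's scans.

## Numerical choices and edge cases

* Intensities are float in [0, 1] throughout; quantization happens only on
  export (8/16-bit TIFF, 8-bit PNG).
* The within-retina axial brightness gradient is exposed but defaults to
  0, so the noise-free per-layer mean equals the configured brightness
  exactly — a property the tests rely on.
* Landmark extraction samples depth by linear interpolation between
  columns; reconstruction uses a monotone spline. The pair is idempotent
  to machine precision when the landmark columns are integers (e.g. width
  501, fovea 250, 51 points) and stable to a few hundredths of a voxel on
  incommensurate grids — the residual is the difference between the two
  interpolants between grid points.
* Zero-thickness target bands in texture transfer are skipped (no voxels
  to fill); zero-thickness *reference* bands contribute their boundary
  value.
* An empty reference for background compositing returns the volume
  unchanged with a warning rather than failing the render.
* Every stochastic function takes an explicit seed; pipeline provenance
  (seeds, coefficients, reference ids, noise levels) rides along in the
  returned objects and in the CLI's provenance JSON.

## Problem sizes in the test suite

The suite exercises the full-size default geometry where counts matter
(landmark arithmetic, default volume dimensions) and a reduced
96 × 5 × 160 phantom geometry elsewhere, chosen so the whole suite runs in
well under a minute: cohorts of 6–20 volumes for model fitting, 10 000
coefficient draws for the bound and moment checks, 100 random 8 × 8
regions for the GLCM oracle, 100 synthetic objects (50 volumes, 50 DME
scenes) for the structural invariants, and 50 null-data repetitions for
the type-I-error calibration of the group comparison.

## Known limitations

The generator synthesizes; it does not fit shapes to images (no
image-driven ASM search), does not segment real data, and does not detect
vessel shadows — locations are supplied or sampled. Thickness statistics
of phantom-trained models describe the phantom population, not any real
cohort; absolute micrometre tables require training on real segmented
volumes, which the I/O layer (long-format CSV, multi-page TIFF, NIfTI)
supports. Sparse-raster geometries make en-face projections blocky in the
B-scan direction, exactly as with real sparse scans.
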