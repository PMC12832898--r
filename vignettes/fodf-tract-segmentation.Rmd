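---
title: "Voxel-wise tract segmentation from full fODF fields: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise tract segmentation from full fODF fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractfodf)
```

## The problem

Diffusion MRI resolves, in every voxel, a *fiber orientation distribution
function* (fODF): a non-negative, antipodally symmetric function on the
sphere describing the orientations of the axon populations passing through
that voxel.  Voxel-wise tract segmentation asks, for each white-matter
tract of interest, which voxels belong to it.  Two anatomical situations
make this hard:

* **Crossing fibers** — two or more differently oriented tracts share a
  voxel, so the local fODF is multi-modal and any single-orientation
  summary is ambiguous.
* **Bottlenecks** — distinct tracts merge into a corridor, run along a
  *common* orientation for some distance, and then diverge toward
  different endpoints.  Inside the corridor the local orientation
  information is identical for both tracts; only spatial context can tell
  them apart.

Peak-based segmentation pipelines compress each voxel's fODF to its top-K
peak vectors (typically K = 3, a 9-channel image) before feeding a
network.  This package instead feeds the *full* spherical-harmonic (SH)
coefficient field to the segmenter, keeping lobes that peak extraction
would discard, and provides the peak representation only as an ablation
input for comparison.

## Representation

fODFs are expanded in the real, orthonormal, *symmetric* SH basis: even
orders $l = 0, 2, \dots, l_{max}$ only, flat coefficient ordering
$j(l,m) = l(l+1)/2 + m$.  At the standard $l_{max} = 8$ this gives

```{r}
count_coefficients(8)
```

coefficients per voxel.  The sign/ordering convention (cosine terms for
$m > 0$, sine terms for $m < 0$, Condon–Shortley phase inside the
associated Legendre functions) follows the convention of MRtrix-style fODF
volumes and is fixed once in `sh_basis_matrix()`, so 45-channel files on
disk have a single unambiguous interpretation.  Orthonormality is
verifiable to machine precision on a Gauss–Legendre product grid
(`gauss_sphere_grid()`), which integrates band-limited products exactly;
the default *projection* design is a deterministic 724-point Fibonacci
hemisphere with ordinary least squares, which recovers any
$l_{max} \le 8$ function to ~1e-15.

Peak extraction (`extract_peaks()`) finds strict local maxima on the
hemisphere grid, refines each by 10 steps of projected gradient ascent on
the sphere (grid-only maxima quantize angles at the ~5° spacing of the
724-point grid; refinement brings recovery below 2° for concentrations
$\kappa \ge 15$ and crossings $\ge 45°$), merges axes closer than 10°,
and discards peaks below 0.1 of the strongest amplitude.  The relative
threshold suppresses noise lobes without hiding genuine secondary fibers;
strictness of the local-maximum test is what makes a perfectly isotropic
profile return *zero* peaks.

## The synthetic phantom

No public fODF dataset is needed for development or testing: the phantom
module generates the two problem structures directly.

* A *tract* is a tube — all voxels within a radius of a 3D polyline — so
  mask geometry has an independent brute-force oracle (point-to-segment
  scan).
* The single-fiber kernel is a normalized **Watson distribution**
  $f(u) \propto \exp(\kappa (u\cdot\mu)^2)$: axially and antipodally
  symmetric, well representable at $l_{max} = 8$ for the default
  $\kappa = 20$, with an unambiguous peak at $\pm\mu$.
* A voxel covered by $k$ tracts receives the fraction-weighted sum
  ($1/k$ each) of their lobes, oriented along the local path tangent,
  plus a constant isotropic background (default fODF value 0.1).
* The **bottleneck** scenario uses two bent tubes whose middle segments
  coincide along a corridor of length $S/3$; inside it both tracts'
  lobes point along the corridor axis with fractions 0.5/0.5, so clean
  peak extraction yields *one* dominant orientation while both masks are
  positive — precisely the ambiguity described above.
* Degradation is i.i.d. Gaussian noise on the SH *coefficients*
  (default $\sigma = 0.02$, roughly 2% of a normalized single-lobe
  amplitude): the pipeline consumes fODFs, not raw diffusion signal, so
  the noise knob lives in the space the model sees.
* Everything is generated from a single integer seed; identical specs
  give bit-identical volumes.

What the phantom does **not** emulate: realistic anatomy (curvature
spectra, cortical terminations, partial-volume CSF/GM), spatially
correlated noise, Rician statistics of the underlying signal, or CSD
fitting artifacts.  Passing phantom tests therefore demonstrates that the
machinery is correct and that the architecture can exploit full-fODF
input — not that real-data accuracy numbers transfer.

## Network, training, inference

The segmenter is a classic 2D encoder–decoder (U-Net): per resolution
level two 3×3 stride-1 convolutions with LeakyReLU (slope 0.01), 2×2
max-pool downsampling, a decoder mirroring the encoder with 2×2
transposed convolutions and equal-resolution skip connections, dropout
0.4 after each encoder block, and a sigmoid 1×1 head.  Full-scale
defaults are depth 5 / 64 base filters (31.1M trainable parameters —
the same order as the ~37M of published full-scale models; exact
per-layer filter counts of those models are not recoverable, so width
and depth are configuration knobs).  Switching the input from 45 SH
channels to the 9-channel peak image changes only the first convolution,
by exactly $9 \cdot 64 \cdot 36 = 20{,}736$ weights.

The network is implemented directly on base-R matrix algebra: im2col +
GEMM convolutions, index-table pooling/upsampling, and a hand-derived
backward pass verified against numerical gradients in the test suite
(worst relative error ~1e-6 on non-negligible gradients).

Training follows the standard recipe for this task: per-element binary
cross-entropy, Adam, cosine-annealed learning rate from 0.002 to 0 over
the epoch budget (no warm restarts), batch size 200 (desk-scale runs use
16), up to 400 epochs with early stopping on validation Dice at patience
50.  Two deliberate choices:

* **One binary model per tract**, with voxels shared by several tracts
  kept in the positive class of every involved tract — overlap is real
  anatomy, not label noise.  The multi-label variant (C-channel sigmoid,
  per-channel BCE) exists for the multi-class comparison; a softmax
  "one label per voxel" reading would contradict overlapping masks.
* **Validation Dice is computed on the fused 3D volume**, not per slice,
  because that is the quantity the method ultimately reports and selects
  checkpoints on.

Slices from all three orthogonal views train a *single* network, which is
then applied per view at inference; the three per-view probability maps
are averaged voxel-wise and thresholded at 0.5.  The threshold is
*strict* (ties negative): the usual "thresholded at 0.5" phrasing leaves
the tie undefined, and a fixed rule makes the pipeline bit-stable — a
fused voxel of (1.0, 0.0, 0.5)/3 = 0.5 is negative.  No
connected-component cleanup or hole filling is applied.  Spatial
flips/rotations are *not* used as augmentation: rotating an fODF image
without reorienting its SH coefficients corrupts the representation.

## Evaluation

All six metrics derive from one voxel confusion count: Dice, volumetric
overlap $\mathrm{VOP} = TP/|G|$, volumetric overreach
$\mathrm{VOR} = FP/|G|$, specificity, precision, Jaccard.  VOR is
normalized by the *reference* volume (the tractometry convention), which
keeps it complementary to precision rather than redundant with it, and
gives the identity $\mathrm{Dice} = 2\,\mathrm{VOP} /
(1 + \mathrm{VOP} + \mathrm{VOR})$ for non-empty references — an
algebraic cross-check the tests enforce.  Metrics on an empty reference
are reported as `NA` sentinels, never silently 0 (phantom tracts can be
absent in edge configurations); aggregation uses the sample (n−1)
standard deviation and logs how many sentinel rows it excluded.

Method comparison uses the two-sided Wilcoxon signed-rank test on paired
per-tract scores — zero differences dropped (Wilcoxon's original
convention; if *all* differences are zero, p = 1), exact null
distribution up to 25 informative untied pairs, normal approximation with
continuity correction beyond — followed by Bonferroni adjustment
$\min(1, m \cdot p)$.

## Numerical and scale choices

* Quadrature: Gauss–Legendre × uniform-azimuth product grids are exact
  for the band-limited integrands used in tests; equal-weight Fibonacci
  grids are reserved for least-squares fitting, where quadrature
  exactness is not needed.
* Peak refinement uses numerical tangent-plane gradients
  (central differences, step 1e-4) with per-candidate step halving —
  robust and dependency-free at the ~1e-2-degree accuracy level actually
  required.
* Default phantom side is 48 (144 is supported to mirror full-resolution
  grids); tests run at sides 16–32.  The end-to-end overfit check trains
  depth-3 / 8-filter networks on a side-32 crossing phantom for at most
  60 epochs — sizes chosen so the whole suite runs comfortably on a
  single CPU while still exercising every stage at full fidelity.
* Input volumes are normalized by the mean order-0 coefficient over
  foreground voxels, making the pipeline invariant to global fODF
  scaling; input scaling conventions vary between CSD implementations,
  so this is applied explicitly rather than assumed.

## Known limitations

* The hand-rolled network trains small configurations briskly but is not
  GPU-accelerated; full-scale (depth-5, 144³, 72-tract) training is out
  of scope here, so published full-scale accuracy tables cannot be (and
  are not) reproduced by this package's tests.
* The phantom's Watson lobes are single-κ and noise is coefficient-space
  Gaussian; claims about robustness to realistic acquisition degradation
  require real data.
* Rotation of SH fields (Wigner-D machinery) is deliberately absent;
  orientation changes are realized by evaluating and re-projecting.
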