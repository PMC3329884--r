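---
title: "Feature-based deformable registration: model, parameters, and phantom design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-based deformable registration: model, parameters, and phantom design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(featwarp)
```

## The method

`featwarp` registers a *template* image onto a *target* image (for example
two respiratory phases of a 4D CT study) in three stages, each exposed as
its own function and orchestrated by `run_registration()`:

1. **Feature detection.** Candidate points are voxels whose local
   neighbourhood carries high gradient energy.  With image intensity $I$
   and central-difference gradient $\nabla I$ (computed per voxel step,
   with replicated edges), the saliency of a voxel is
   $\sum_{3\times3\times3} \lVert\nabla I\rVert^2$ over its neighbourhood.
   Voxels inside a tissue intensity window are thresholded on saliency,
   non-maximum suppressed, and capped in count.

2. **Descriptor matching.** Each feature point is signed with a
   quadrant-wise gradient orientation histogram: the $8^3$-voxel window
   around the point is split into eight $4^3$ octants, and for each octant
   and each coordinate plane (xy, yz, zx) the in-plane gradient
   projections are binned by angle into eight 45° bins, accumulating
   in-plane magnitude: $8 \times 3 \times 8 = 192$ components.  Points are
   associated by the least-squares descriptor difference
   $S = \sum_{\alpha=1}^{192} \lvert (\nabla I)_\alpha - (\nabla I')_\alpha \rvert^2$:
   for each template point the two best target candidates give $S_1 \le
   S_2$, and the association is accepted only when the ratio
   $\kappa = S_1/S_2$ is below 0.5, so ambiguous correspondences are
   dropped rather than guessed.  A bidirectional pass then re-matches each
   accepted target point back against the template set and keeps only
   mutual best matches.

3. **Thin-plate-spline interpolation.** The surviving pairs become control
   points of a TPS: with kernel $U(r) = r^2 \log r^2$, kernel matrix $K$,
   affine block $P = [\mathbf 1 \mid p_i]$, and bordered system
   $L = \begin{bmatrix} K & P \\ P^\top & 0\end{bmatrix}$, solving
   $L \, [W \mid a]^\top = Y$ per output component yields weights $W$ and
   affine coefficients $a$ such that
   $f(x) = a_1 + a_u u + a_v v + a_w w + \sum_i w_i U(\lVert p_i - x\rVert)$
   interpolates every control point exactly and minimizes bending energy.
   The model is densified into a displacement field and used to
   backward-warp the template.

### Assumptions

* Both images live on axis-aligned regular grids; all computation is done
  in physical millimetres, so anisotropic spacing is handled, but
  direction cosines are not supported.
* Deformations are smooth and moderate: descriptors are not invariant to
  rotation or scale, so the method degrades when local strain within an
  $8^3$ window becomes large (tens of percent).
* The displacement convention is **target → template** (backward
  warping): the field at a target voxel points to its source position in
  the template.  The TPS is fitted with source = target landmarks and
  destination = template landmarks, so the dense field has no holes.
  Phantom ground truth is stored in the same frame, making estimated and
  true fields comparable by direct subtraction.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `intensity_window` | (0, ∞) | image units | Tissue selection (CT-like: soft tissue 0–100, bone > 100).  Also excludes the air–tissue partial-volume shell, whose long self-similar edge breeds ambiguous matches. |
| `saliency_quantile` | 0.6 | — | Keeps the most structured 40% of in-window voxels.  Sparser detection (e.g. the 90th percentile) leaves so few control points that a single residual mismatch corrupts a large TPS neighbourhood. |
| `nms_radius` | 3 | mm | Non-maximum suppression spacing; ties broken by lexicographic voxel index for determinism. |
| `max_points` | 10 000 | — | Cost cap; matching is quadratic in the feature count. |
| `kappa_threshold` | 0.5 | — | The ratio test on squared distances; "less than 50%" discards ambiguous associations. |
| `search_radius` | 30 | mm | Plausible-motion prior.  Respiratory soft-tissue displacement rarely exceeds ~3 cm; without the bound, distant lookalike structures occasionally pass both the ratio and bidirectional tests, and a single such pair ruins the exact-interpolation TPS.  Set `NULL` for an unrestricted search. |
| `kernel` | `r2logr2` | — | $U(r) = r^2\log r^2$ in both 2D and 3D, as is customary in the medical-registration use of TPS; the 3D biharmonic kernel $U(r)=r$ is available as an option. |
| `ridge` | 0 | — | Exact interpolation.  A positive value relaxes the fit for noisy control points (not used by default). |

Descriptor histograms are magnitude-weighted (the classical convention);
count weighting and unit-L2 normalization are available as options.  In
our phantom experiments normalization *hurt* match purity, so it stays
off by default.

## The digital phantoms

Real reference data for this problem (clinical CT, physical deformable
phantoms) cannot ship with a package, so `featwarp` includes a synthetic
phantom family with exact ground truth:

* **Geometry.** An ellipse/ellipsoid "body" of soft-tissue base intensity
  (40) on an air background (−1000).
* **Texture.** Gaussian blobs with log-uniform length scales 4–16 mm and
  amplitudes 60–180, dense enough that every descriptor window contains
  several overlapping structures.  This mimics the property of real
  tissue that makes SIFT-style matching work: heterogeneous multi-scale
  contrast.  It does *not* reproduce CT noise spectra, streak artifacts,
  bone/air interfaces inside the body, or sliding organ boundaries — so
  passing phantom studies demonstrate correctness of the machinery and
  realistic-texture accuracy, not clinical performance.
* **Markers.** Rigid spheres (radius 5 mm, contrast +400) with a
  one-voxel linear edge blend, placed with a minimum separation;
  their centres transport analytically under any deformation, giving
  exact target-registration-error evaluation.
* **Deformations.**  The 2D harmonic warp
  $x' = (1 + b\cos m q)\,x$, $q = \tan^{-1}(y/x)$, with $b$ the magnitude
  and $m$ the complexity; a smooth 3D field built from Gaussian-windowed
  displacement lobes; and rigid translations for exactness tests.
  Invertibility is checked at construction ($|b|(1+m/2) < 1$ for the
  harmonic map; total slope below 1 for lobe fields).

Two standard studies wrap phantom + pipeline + evaluation:

* `harmonic_phantom_study()`: a 170×170 slice at 2 mm (body ≈ 28 × 30 cm),
  deformed with $b = 0.13$, $m = 2$ about the body centre — peak
  displacement $0.13 \times 140\,\text{mm} = 18.2$ mm at the lateral body
  edge.  Accuracy is summarized over in-body pixels against the analytic
  field; background is excluded because a feature-based method places no
  control points in air, making extrapolation there meaningless.
* `marker_phantom_study()`: a 128³ volume at 2 mm with 24 embedded
  spherical markers, deformed by a three-lobe smooth field (main lobe
  18 mm peak, 60 mm length scale — the scale of a diaphragm push with a
  1.8 cm tumour excursion).  The headline statistic is the fraction of
  markers whose registration residual is below 2 mm.

These problem sizes run in roughly a second (2D) and about 90 seconds
(3D) on one core; they are the sizes used by the package's test suite and
acceptance script.

## Numerical choices

* **Descriptor window.** The even 8-voxel window spans offsets −4…+3
  around the centre voxel along each axis; octants split at offset 0.
  Angles are mapped to $[0°, 360°)$ with half-open bins, so an angle
  exactly on a bin edge goes to the higher bin; zero-magnitude in-plane
  projections contribute nothing.  Plane angles are measured as
  atan2(gy, gx), atan2(gz, gy) and atan2(gz, gx) for the xy, yz, zx
  planes.
* **2D images** (any single-slice grid) use an 8×8 window, four 4×4
  quadrants, and the xy plane only: 32 components, never comparable with
  3D descriptors.
* **Degenerate matches.** $\kappa \equiv 0$ when $S_2 = 0$; ties for
  $S_1$ or $S_2$ go to the target point with the smaller lexicographic
  voxel index.  Distance matrices are computed with the polarization
  identity and cancellation noise below $10^{-10}\times$ the descriptor
  norm scale is snapped to zero so that identical descriptors give
  exactly $S = 0$.
* **Voxel indices** are 1-based (the R convention); the physical
  coordinate of voxel $(i,j,k)$ is `origin + (c(i,j,k) - 1) * spacing`.
* **TPS solve.** Dense LU on the bordered system; duplicate source points
  (closer than $10^{-6}$ mm) are merged with averaged destinations,
  collinear/coplanar configurations are rejected.  Exactness at control
  points is tested to $10^{-6}$ mm for up to 50 control points.
* **Phantom resampling.** The harmonic map is inverted per pixel by
  bisection on the radial equation (the warp factor is bounded by
  $1 \pm |b|$, which brackets the root); lobe fields by fixed-point
  iteration (contractive because the slope bound is below 1).  Both to
  $10^{-6}$ mm.  Images are resampled by linear interpolation with a
  background fill.

## Known limitations

* No rotation/scale invariance and no multi-resolution scheme: large or
  sliding motion outside the search radius will not be recovered.
* Exact TPS interpolation trusts every surviving control point; a wrong
  pair inside the search radius distorts its neighbourhood.  The defaults
  (dense detection, ratio test, bidirectional filter, bounded search)
  make this rare on textured inputs, but featureless or periodic images
  remain adversarial.
* MetaImage support covers uncompressed, axis-aligned files only; NIfTI
  files with non-identity orientation are rejected rather than resampled.
* The 2D descriptor (32 components) is inherently less discriminative
  than the 3D one; 2D results benefit from denser texture.
```{r session}
sessionInfo()
```
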