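---
title: "Markerless multi-view 3D localization of skin features: methods and design"
author: "dermatrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless multi-view 3D localization of skin features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermatrack)
```

## The problem

Surgical navigation needs a stable reference attached to the patient.
Conventional systems track adhesive optical markers or bone-mounted
frames; both complicate the workflow and can be dislodged or occluded.
Natural skin features — moles and pigment spots — are blob-like, dark,
and distributed over the surgical field, and a rig of several calibrated
grayscale cameras sees each of them from multiple directions. If those
blobs can be detected, matched across views, and triangulated at
sub-millimetre consistency, the skin itself becomes the tracking target.

`dermatrack` implements that localization chain and, because clinical
image data of this kind is restricted, ships a fully ground-truthed
synthetic camera-rig simulator so every stage can be validated
quantitatively.

## Pipeline

For an analyzed region and a selected camera pair the stages are:

1. **Intrinsic correction** — each image is resampled to the ideal
   pinhole geometry, inverting polynomial radial (`k1,k2,k3`) and
   tangential (`p1,p2`) lens distortion. The inversion is a fixed-point
   iteration (10 iterations, tolerance 1e-8 px). With all coefficients
   zero, the image is returned bit-exact.
2. **CLAHE** — contrast-limited adaptive histogram equalization makes
   faint pigment spots separable without globally amplifying noise. The
   image is partitioned into a tile grid; each tile's histogram is
   clipped at `clip_limit` × tile mass, the excess is redistributed
   uniformly over all bins in a single pass, and per-pixel output blends
   the four surrounding tile transfer functions bilinearly. Defaults
   (8×8 tiles, clip 0.01, 256 bins) are conventional CLAHE settings;
   they are recorded in the configuration so runs are reproducible.
   Undistortion precedes CLAHE because the geometry must be metric
   before any coordinate-bearing step.
3. **Rectification** — with full calibration the pair is rotated onto a
   common plane whose x-axis is the baseline (shared averaged
   intrinsics), so corresponding points land on equal rows; matched
   noiseless projections agree in row to well under 0.5 px. A fallback
   works from point correspondences alone: the second epipole is mapped
   to infinity and the first view follows via the matching projective
   transform that minimizes horizontal disparity. Both paths return
   invertible pixel homographies; a shared vertical offset preserves
   row alignment. If an epipole falls inside an image, rectification is
   refused (the rig geometry is then unusable for scan-line matching).
4. **Detection** — two complementary blob detectors, both run on the
   rectified, equalized images:
   * *MSER* reports connected components of threshold level sets whose
     area is stable across ±`delta` levels (local minimum of relative
     area variation along the component tree, ≤ `max_variation`, area
     within bounds). Both polarities are detected. Co-located nested
     regions are kept deliberately — a dark mole with a darker core is
     real signal — and pruned only at the 3D stage. The component tree
     is built incrementally in C++; an exhaustive 256-threshold sweep
     oracle in the test suite checks exact region-set equality.
   * *Fast-Hessian* ("SURF-style") evaluates box-filter approximations
     of the scale-normalized Hessian determinant on a summed-area table
     over an octave/scale pyramid and keeps 3×3×3 scale-space maxima
     above a threshold, refined by a quadratic fit. The default
     threshold (15) was tuned once on the bundled synthetic fixture.
5. **Description** — an upright 64-d SURF-style descriptor per feature:
   4×4 subregions of Haar-wavelet response sums (Σdx, Σ|dx|, Σdy,
   Σ|dy|) over a 20s window, Gaussian-weighted, unit-normalized.
   Orientation assignment is deliberately omitted: rectification has
   already removed in-plane rotation between the views, so rotation
   invariance would only discard discriminative information. Features
   on constant patches yield zero vectors and are flagged unmatchable.
6. **Scan-line matching** — candidates must lie within `band` rows
   (default 2, absorbing rectification residuals) and within the
   disparity range; per feature the minimal-SSD candidate is taken;
   mutual-best filtering enforces one-to-one matching and a ratio test
   (default 0.8) suppresses ambiguous matches. On unit vectors
   SSD = 2(1−cosine). The extra filters beyond bare minimal-SSD are
   disclosed, configurable, and can be disabled.
7. **Sub-pixel refinement** — matched centers are mapped back to the
   original undistorted images and recentred on the intensity-weighted
   centroid of the background-subtracted blob, inside a window of
   2.5 × scale. The local background is an affine plane fitted
   robustly to the window border ring; a constant background estimate
   is measurably biased by lateral illumination gradients, which are
   ubiquitous under surgical lighting.
8. **Triangulation** — each match's two viewing rays rarely intersect;
   the triangulated point is the midpoint of their common
   perpendicular, and the segment length is the *triangulation error*
   `e` (mm), the per-feature localization quality metric. The midpoint
   construction is used (rather than linear-SVD triangulation) because
   the error metric is defined as that segment length. Rays are
   declared parallel below a sine of 1e-8. The camera pair for a region
   is the admissible pair with the widest vergence angle at the region
   center.
9. **3D outlier removal** — scan-line matching alone admits ghost
   correspondences (features of different blobs on the same epipolar
   line triangulate to consistent but wrong 3D points). Approximating
   the skin patch as a plane, MSAC (truncated squared-residual scoring)
   fits the plane and discards features beyond the distance threshold
   (default 1 mm, 1000 hypotheses, seeded). When the number of distinct
   point triples is within the iteration budget, all triples are
   enumerated — deterministic and never worse than sampling. An
   orientation prior (normal within 60° of the rig viewing axis)
   mirrors the mechanically known rig-to-skin geometry. The *discard
   ratio* is matched features per surviving inlier.
10. **Area and statistics** — inliers are projected orthogonally onto
    the plane, Delaunay-triangulated in plane coordinates (via
    `deldir`), and triangle areas are summed (cm²); for a convex
    scatter this equals the hull area. Per region the report gives
    feature count, density per cm², the error distribution (mean,
    sample SD, RMS, min, quartiles, max) and the discard ratio;
    quartiles use linear interpolation of order statistics (type 7).
    The pooled "TOT" row is recomputed from the concatenated error
    vector, never averaged from per-region rows.

The marker benchmark reuses the same machinery on the bright circular
markers: binarization (Otsu restricted to intensities at or above the
median — plain Otsu on a skin image is captured by the dark mole tail
and splits skin from moles rather than markers from skin; a manual
threshold override is available), per-component detection, scan-line
correspondence, midpoint triangulation by the same code path, and
greedy nearest-neighbour assignment (cap 2 mm) to the known marker
coordinates.

## The synthetic scene generator

`scene_config()` + `render_scene()` emulate the measurement situation:
a near-planar skin patch (70 × 50 mm) at the center of a four-camera
rig mounted like the corners of a flat detector 450 mm above it
(f = 1800 px at 512 × 384; a 2592 × 1920 preset mirrors the clinical
resolution). The patch carries:

* 20 dark elliptical blobs, radius 0.8–2 mm, intensity 40–110 on a
  background of 170, axis ratio up to 1.5, and 0.2 mm out-of-plane
  jitter — skin is not perfectly flat, so the MSAC stage has realistic
  work to do;
* 5 bright circular markers (radius 3 mm, intensity 250) lying exactly
  on the plane;
* a lateral illumination gradient (15 grey levels across the image);
* optional noise: `noise_intensity` (additive Gaussian grey levels) and
  `noise_px` — an independent per-camera jitter of each object's
  rendered position that emulates the view-inconsistency which
  detection and calibration errors produce, and which drives the
  triangulation error.

Objects are rasterized analytically: supersampled pixel rays are
intersected with the object plane and tested against the ellipse, then
box-averaged (8× per axis) and quantized to 8 bits. Rendering is
deterministic given the seed, and the ground truth (3D centres and
their analytic projections, consistent with the calibration to 1e-9 px)
is exported alongside.

What the simulator does *not* model: skin texture and specular
reflection, curvature beyond the out-of-plane jitter, breathing motion,
occlusions, and blob appearance variation between views. Passing the
synthetic end-to-end checks therefore demonstrates the geometry,
detection and matching machinery is correct and noise-robust in the
stated regime — not that clinical imagery of arbitrary quality will
reach the same numbers.

## Numerical choices and edge cases

* Pixel coordinates are 0-based, x right, y down, origin at the center
  of the top-left pixel; world units are millimetres throughout.
* The fundamental matrix is estimated with the normalized eight-point
  algorithm; rank 2 is enforced by zeroing the smallest singular value,
  and F is scaled to unit Frobenius norm with its largest-magnitude
  entry positive (column-major first on ties) for determinism.
* Feature ensembles are sorted by (y, x, scale) before indexing;
  SSD ties break by smaller row difference, then smaller index; MSAC is
  seeded and enumerates exhaustively when feasible — all so that two
  runs of the same configuration are byte-identical.
* Degenerate inputs are contracts, not crashes: fewer than 8
  correspondences, collinear point sets, parallel rays, epipoles inside
  the frame, planes from fewer than 3 points, and empty ROIs all raise
  (or, where the spec of the stage calls for it, return empty results).
* Box sums at real-valued coordinates interpolate the summed-area
  table bilinearly, which is exact for a piecewise-constant image.

## Known limitations

The dominant accuracy floor on clean images is the *eccentricity error*
of circular-target localization: under perspective, the centroid of a
projected ellipse is not the projection of the disc's 3D center. For
millimetre-scale blobs viewed ~17° off-normal at 450 mm this bias is of
order 0.005–0.05 px per view and differs between cameras, leaving a
residual ray skew of roughly 1–3 µm at the default test scale. It is a
property of centroid-based localization of extended circular targets,
not of this implementation; correcting it would require estimating each
blob's 3D radius and orientation and applying a conic pole-polar
correction, which is out of scope here. Consequences and measured rates
are asserted by the end-to-end test on the noiseless scene.

Other limitations: a single plane per region (curved-surface models are
out of scope), per-acquisition localization (no temporal tracking), and
manual/config-driven region selection.

## Problem sizes used by the checks

The bundled validation uses deliberately modest sizes so the whole
suite replays quickly on one CPU: 512 × 384 images, 20 blobs and 5
markers per scene, 10 seeds per noise level in the noise-monotonicity
check, randomized MSER oracle images up to 24 × 24 (where the
exhaustive 256-threshold component tree is cheap), and exhaustive MSAC
comparisons up to 25 points. The statistical behaviour these sizes
probe — oracle equalities are exact, and the noise sweep uses means
over seeds — does not depend on scaling them up.
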