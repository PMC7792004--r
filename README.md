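# dermatrack

Markerless multi-view 3D localization of skin features for surgical
patient tracking.

Surgical navigation conventionally tracks adhesive optical markers on
the patient's skin. `dermatrack` implements the markerless alternative:
natural skin blobs (moles, pigment spots) are detected in the images of
a calibrated multi-camera rig with **MSER** (maximally stable extremal
regions) and a **fast-Hessian** (SURF-style) detector, described with
upright 64-d SURF-style descriptors, matched along rectified epipolar
scan lines by descriptor SSD, and triangulated. For a matched feature
with back-projected rays `r_i`, `r_j`, the triangulated point is the
midpoint of the shortest segment connecting the rays and the segment
length is the per-feature **triangulation error** `e` [mm]. A plane is
then fitted to the 3D cloud with **MSAC** (truncated squared-residual
RANSAC) to discard ghost matches, the analyzed skin area is estimated
from a Delaunay triangulation of the plane-projected inliers, and the
error distribution (mean, SD, RMS, quartiles, features/cm², discard
ratio) is reported per region and pooled. Bright circular optical
markers can be localized by the same chain and benchmarked against
known 3D coordinates by Euclidean distance.

Because clinical multi-view skin imagery is restricted, the package
includes a fully ground-truthed **synthetic scene simulator**: a
near-planar skin patch with dark elliptical blobs and bright markers,
rendered analytically through a configurable convergent 4-camera rig
with controllable noise and illumination, exporting exact 3D ground
truth. Every pipeline stage is validated against independent
brute-force oracles in the test suite.

## Worked example

```r
library(dermatrack)

# a reproducible synthetic acquisition: 4 cameras, 20 blobs, 5 markers
scene <- render_scene(scene_config(seed = 7))

report <- run_localization(scene$images, scene$cameras, detector = "MSER")
print(report)
#> <localization_report>
#>   region 1 / MSER: pair 1|3, detected 416+428, matched 168, inliers 168, mean e 0.0066 mm, area 20.78 cm^2
#>   TOT MSER: n 168, mean 0.0066, sd 0.0105, rms 0.0124 mm, 8.1 features/cm^2, discard 1.00

bench <- benchmark_markers(scene$images, scene$cameras,
                           scene$ground_truth$markers)
print(bench)
#> <marker_benchmark> MSER, pair 2|4, 5 marker(s) assigned
#>                     n   mean     sd    rms    min     q1 median     q3    max
#> triangulation_error 5 0.0172 0.0094 0.0191 0.0082 0.0091 0.0173 0.0199 0.0314
#> euclidean_distance  5 0.0368 0.0087 0.0376 0.0269 0.0330 0.0354 0.0381 0.0504
```

The report reads: on the selected widest-vergence camera pair, 168
matched blob features survived plane-based outlier removal with a mean
ray-consistency (triangulation) error of a few micrometres on this
noiseless scene, spread over ~20 cm² of skin; the five optical markers
were relocated within 0.04 mm of their ground-truth 3D positions. With
realistic view-inconsistency noise (`noise_px = 0.5`), the mean
triangulation error rises to ≈ 0.1–0.2 mm — the sub-millimetre regime
that makes skin-feature tracking viable for navigation.

Individual stages are exported too: `detect_mser()`,
`detect_fast_hessian()`, `extract_descriptors()`,
`match_scanline_ssd()`, `triangulate()`, `msac_plane_fit()`,
`estimate_area()`, `clahe()`, `rectify_pair()`, and friends; see the
vignette (`vignettes/skin-feature-localization.Rmd`) for the model,
parameter meanings, and design rationale.

A thin command-line front end lives in `inst/cli/dermatrack`:

```sh
Rscript inst/cli/dermatrack simulate --seed 1 --out-dir scene/
Rscript inst/cli/dermatrack localize --dir scene/ --detector mser --out-dir out/
Rscript inst/cli/dermatrack benchmark-markers --dir scene/ --markers scene/gt_markers.csv
```

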