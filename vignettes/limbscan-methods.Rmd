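---
title: "Methods: multi-view RGB-D reconstruction of limb-like objects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-view RGB-D reconstruction of limb-like objects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`limbscan` reconstructs a closed surface mesh of a convex, limb-like
object — a plaster cast mold or a residual limb — from five simultaneous
RGB-D views taken by cameras fixed on an enveloping frame. This vignette
explains the model behind each stage, the tunable parameters and why their
defaults are what they are, the numerical choices that matter, and what
the synthetic test bed does and does not demonstrate about real captures.

## Rig geometry and the design equations

The rig places four cameras every 90° on a circle of radius 305 mm, optical
axes meeting on the rig axis, each camera in a vertical stance so the wide
image axis (1280 px, 69.4° field of view) runs along the limb; a fifth
camera on the axis views the distal end. The design chain that sizes this
rig is exposed directly: a 470 mm leg circumference gives a 75 mm target
radius (`circumference_to_radius()`), the standoff is the frame radius
minus the target radius (230 mm), the view extent at that standoff is
`2·tan(fov/2)·l` (318.5 × 178.9 mm), and the resolution is extent over
pixels, ≈0.249 mm/px. One printed-value convention is worth naming: the
design chain quotes that resolution *truncated* to two decimals (0.24);
ordinary rounding would give 0.25, so reports that compare against the
quoted figure truncate.

Pixels are 0-based with `(u, v) = (column, row)`; the camera frame is
right-handed, +z into the scene, +y down. Depth rasters hold millimetres
with 0 marking invalid pixels, and color is assumed factory-aligned to
depth, so deprojection is the plain pinhole map — no distortion model, by
design: the hardware this emulates performs undistortion and alignment
on-device.

## Extrinsic calibration by Kabsch superposition

Every camera sees the same 6×9 checkerboard (54 inner corners, 25 mm
squares, row-major order). Calibration consumes *3D* corner coordinates in
each camera frame; 2D corner detection is deliberately out of scope, which
keeps the module hardware-free and exactly testable. For each camera the
Kabsch algorithm aligns the board model onto the observation: centre both
sets, form the 3×3 cross-covariance `H = PᵀQ`, decompose `H = V S Wᵀ`,
and assemble the proper rotation with the reflection guard
`d = sign(det(W Vᵀ))`. A note on conventions: with points as matrix rows,
the literal product `W·diag(1,1,d)·Vᵀ` is the rotation carrying the
*reference* set onto the observation; the module contract wants the
opposite direction (map Q onto P), so the implementation uses its
transpose `V·diag(1,1,d)·Wᵀ`, with the translation completed as
`t = centroid(P) − R·centroid(Q)`. The returned RMSD is the aligned
residual. Camera poses are chained through the board:
`extrinsic_i = (ref-from-board) ∘ (cam_i-from-board)⁻¹`, so the reference
camera (camera 1 by default, configurable) is the global frame.

Accuracy under noise, measured on this rig geometry by Monte Carlo
(50 draws of isotropic 0.5 mm corner noise, 5 cameras): rotation error
mean ≈0.13°, translation error mean ≈0.6 mm, with 95th percentiles
≈0.28° and ≈1.5 mm. The 95th percentile is the statistic the acceptance
checks assert (below 1° / 2 mm); the absolute worst of 250 half-normal
draws is lever-arm dominated (the end camera sits ~355 mm from the board)
and occasionally grazes 2 mm, which is why a robust quantile, not the max,
is the reported accuracy figure.

## Segmentation

The capture scene is engineered — target in front of a green sheet — so
segmentation is a short, deterministic chain rather than a learned model:

1. **Depth cut** at `depth_max_mm = 500`: keeps `0 < z ≤ 500`, removing
   the backdrop (placed at 600 mm) in one stroke.
2. **Color removal** in HSV: pixels inside H ∈ [70°, 170°], S ≥ 0.25,
   V ≥ 0.2 (any darker or brighter green) are dropped. The bounds are
   configurable; hue wrap-around intervals are supported.
3. **Otsu binarisation** of the luma restricted to the surviving support
   (outside pixels set to 0), i.e. the threshold maximising the
   between-class variance over a 256-bin histogram, with `value >
   threshold` as the binarisation rule. Where the criterion is flat — a
   perfectly bimodal image — the midpoint of the maximising run is taken,
   so the threshold lands between the modes rather than at the lower one.
   Bright plaster-like targets then vote white, shadows black.
4. **Largest 8-connected region**: the target is assumed to be the
   biggest remaining blob. Ties break to the region whose first pixel
   comes earliest in reading order. When lighting breaks this assumption
   (the real-world failure mode), the automatic choice errors out and a
   `seed_pixel` lets the operator pick the region — an explicit override,
   never a silent fallback.
5. **Binary median**, 15×15 window, 10 passes, reflect padding — for a
   binary mask this is a majority vote, and the odd window count excludes
   ties. Smooths the ragged color-filter rim.
6. **Erosion**, 3×3 window, 10 passes, out-of-bounds counting false —
   trims ~10 px from the rim, discarding exactly the mixed edge pixels
   whose depth is least trustworthy.

The median can bleed a pixel or two past the depth support, so the mask is
clipped back to the depth∧color support before erosion: the final mask
never contains a pixel the depth threshold rejected. Erosion costs Dice
score by design (≈0.95 against the true silhouette on clean renders): the
trimmed rim is re-observed by neighbouring views, so the pipeline trades
silhouette completeness for point-cloud cleanliness.

All morphology runs on summed-area tables (window sums), which makes a
15×15 majority vote the same cost as a 3×3 one; Otsu, the labelling and
both filters are each tested for exact equality against naive
brute-force oracles.

## Registration

Masked frames deproject to per-camera clouds (colors carried along).
Fusion then proceeds exactly in rig order, which is an explicit,
operator-supplied configuration field — the physically adjacent view
overlaps most, and no automatic ordering is attempted:

1. Apply the calibrated extrinsics (global alignment) and voxel-downsample
   each cloud at `voxel_size_mm = 2` (one centroid per occupied 2 mm cube;
   attributes averaged, normals re-normalised). The 2 mm grid matches the
   downsampling scale the capture pipeline uses for processing speed.
2. Fix the first cloud. For each subsequent view, estimate target normals
   (PCA over k = 30 neighbours) on the *accumulated* merged cloud and
   refine the view against it with point-to-plane ICP; refining against
   the accumulation rather than only the previous view improves loop
   closure around the ring of cameras.
3. Concatenate and downsample once more.

The ICP minimises `E(T) = Σ ((p − T·q)·n_p)²` over correspondences within
`max_correspondence_mm = 10` (nearest neighbour by kd-tree, ties to the
smallest index). Each iteration solves the small-angle linearisation — row
`[q × n, n]`, right-hand side `−(q − p)·n` — via the 6×6 normal equations
(Cholesky, with a 1e-12 ridge so flat directions stay put), applies the
Rodrigues exponential of the solution, and re-evaluates. An update that
would increase `E` is rejected and iteration stops, so the objective is
non-increasing by construction; convergence is declared when the relative
decrease falls below 1e-6, with a 50-iteration cap. The correspondence
threshold is a genuine free parameter of the method (its operational value
is not pinned by the capture protocol this emulates); 10 mm comfortably
exceeds the calibration error that ICP is asked to absorb.

One geometric caveat shapes the tests: a lathe-symmetric target leaves
rotation about its own axis unobservable to any point-to-surface
criterion. Pose-recovery assertions therefore use an asymmetric
plane-plus-bumps sample (recovery of a 2°/3 mm perturbation to within
0.1°/0.2 mm), while phantom-based checks assert distance-to-surface,
i.e. pose modulo the symmetry.

## Surface reconstruction and closing

The fused oriented cloud becomes a mesh via an implicit reconstruction
with the same input/output contract as screened Poisson plus mesh repair
(oriented points in, closed mesh out), built from primitives that are
exactly testable:

* a **truncated signed-distance field** on a regular lattice over the
  padded bounding box — at each node, distance to the nearest cloud point,
  signed by that point's normal, truncated at `bandwidth_mm` (default 6 mm
  = 3× the fusion voxel), then one 6-neighbour averaging pass;
* **marching tetrahedra** on the Freudenthal 6-tetrahedra cube split.
  Unlike marching cubes there are no ambiguous sign cases, and the split
  assigns every cube face the same diagonal under translation, so the
  zero surface is watertight whenever it stays inside the grid. Exact
  zeros are nudged off the lattice by 1e-12 so vertices never coincide
  with nodes.

The lattice default is `grid_resolution = 128` nodes along the longest
box edge (≈2.9 mm cells for the default phantom), padding 5 % of the box
(at least 1.5 bandwidths). The backend is an ordinary function argument,
so a library Poisson implementation can be swapped in without touching
the callers.

Views never see the underside where the object meets its support, so the
raw iso-surface has a boundary there; `close_mesh()` walks each boundary
loop (directed boundary edges chained end-to-end; more than one face per
edge is rejected as non-manifold) and caps it with a centroid fan wound
opposite to the rim, preserving orientation. This is where the
characteristic flat base of the reconstructed mold arises — it is a
consequence of capping, not a modelling choice. Volume comes from the
signed tetrahedron sum, orientation-corrected.

## Validation metrics

Dice (`2|A∩B|/(|A|+|B|)`) compares binary masks; the symmetric Hausdorff
distance compares masks (pixel-centre coordinates, pixel units) or point
sets (mm); `nearest_distances()` exports the per-vertex field used for
distance heat maps (written into PLY as a `quality` property). Summary
rows report min, quartiles, median, mean, max, IQR and RMS; quartiles use
linear interpolation between order statistics (R's default type 7 — the
convention is stated because IQR computed from independently rounded
quartiles can differ in the last digit), and RMS is `sqrt(mean(x²))` of
the data values themselves. Mask Hausdorff values convert to millimetres
through the design resolution (`px_to_mm`). `cross_section_extent()`
intersects a mesh with a plane at a given height and measures the section
extent along a chosen direction — the diameter-at-height verification a
prosthetist performs with calipers.

## The synthetic scene

The simulator replaces the physical rig with constructs whose geometry is
known in closed form:

* **Phantom**: a piecewise-linear radius-vs-height profile revolved about
  the z axis, flat base, hemispherical distal cap. The default profile
  (radii 70→75→60→40 mm at heights 0/50/150/210 mm, 40 mm cap, 250 mm
  overall) matches the design chain's 75 mm maximum radius and a
  residuum-like taper. Skin-tone surface color; green backdrop at 600 mm
  from each camera so the 500 mm depth cut separates it, mirroring the
  green-sheet setup.
* **Rendering**: analytic per-pixel ray casting — each profile segment is
  a cone frustum (one quadratic per ray), plus cap sphere and base disk —
  with no rasterisation or z-buffer quantisation, so rendered depth equals
  the true ray range to machine precision and every downstream stage has
  an exact oracle. Depth is stored continuously in memory and quantised to
  integer millimetres only at the 16-bit PNG boundary, as the sensor
  format does.
* **Depth noise**: Gaussian with σ(z) = 0.02·(z/2000)·z, the
  range-proportional model behind a "≤2 % at 2 m" accuracy contract; at
  the 230–380 mm working range this is ≈0.3–1.5 mm. Seeded and
  reproducible.
* **Checkerboard**: corner coordinates transformed into each camera frame,
  optional corner noise; corners strictly behind a camera are a visibility
  error.

What this test bed does *not* emulate: stereo-matching artefacts
(speckle, edge fattening, holes), lens distortion, exposure and lighting
variation, motion during capture, and soft-tissue deformation. Passing
tests therefore demonstrate the correctness and noise-robustness of the
algorithms, not the field performance of a physical scanner; the
depth-noise model is the one deliberate bridge between the two.

## Problem sizes and determinism

Unit and orchestration tests run the simulator at 320×180 with
proportionally smaller morphology windows (5×5 median ×3, 3×3 erosion
×2) — the full-size windows would eat a 4×-smaller silhouette — while
every acceptance check runs the full 1280×720 five-camera conditions, a
128 lattice, and the default phantom. A complete five-view simulate +
reconstruct cycle takes on the order of a minute on one CPU. All file
writers are deterministic (fixed float formatting, seeded noise, stage
logs with input checksums), so re-running a completed workspace rewrites
byte-identical artefacts.

## Known limitations

* Convex (or near-convex) targets only: one shell is assumed, and
  occlusion-free coverage by five views is a premise, not a result.
  The default phantom's cap joins the shaft with a small slope
  discontinuity, so its silhouette is convex only up to that junction —
  harmless here, but a reminder the convexity premise is about the
  target class, not enforced by code.
* The reconstruction lattice bounds accuracy at ~cell size; fine surface
  detail below ~3 mm is smoothed at the default resolution.
* Rotation about a rotationally symmetric target's axis is unobservable
  to ICP; real residua are asymmetric enough in practice, and the
  simulator's validation metrics are symmetry-aware.
* Calibration quality is bounded by the corner-coordinate quality it is
  fed; there is no bundle adjustment across cameras.
* No colored ICP, no global pose-graph optimisation, no automatic camera
  ordering: registration follows the configured physical order.
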