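# limbscan

Multi-view RGB-D capture, registration and surface reconstruction for
residual-limb scanning, as an R package.

Prosthetic sockets are still shaped around hand-made plaster casts of the
residual limb (the residuum). A desk-scale multi-view scanner replaces the
cast with a digital surface model: five RGB-D cameras on an enveloping
frame — four spaced every 90° on a 305 mm-radius circle plus one end-view
camera — image the limb simultaneously, and a software pipeline turns the
five color + depth image pairs into a closed, watertight triangle mesh a
prosthetist can measure and archive. `limbscan` implements that pipeline
end to end, with a hardware-free synthetic scene simulator standing in for
the physical rig, so every stage runs and is testable on a desk.

The stages, and the mathematics at their core:

* **Camera geometry** — pinhole design equations (`f = (B/G)·l`,
  `res = G/B`, `w = 2·tan(fov/2)·l`) for choosing standoff and resolution,
  plus exact deprojection `x = (u−cx)·z/fx`, `y = (v−cy)·z/fy` of aligned
  RGB-D frames into point clouds.
* **Extrinsic calibration** — Kabsch rigid superposition: centre both
  corner sets, `H = PᵀQ`, SVD `H = V S Wᵀ`, sign guard
  `d = sign det(WVᵀ)`, rotation assembled from `V, diag(1,1,d), W`;
  camera poses chained through a shared 6×9 checkerboard and reported
  with the residual RMSD.
* **Segmentation** — 500 mm depth cut, HSV green-sheet removal, Otsu's
  threshold (maximising the between-class variance
  `ω₀ω₁(μ₀−μ₁)²`), largest 8-connected region, 15×15 binary median
  (10 passes), 3×3 erosion (10 passes).
* **Registration** — voxel-grid downsampling at 2 mm, PCA normal
  estimation, point-to-plane ICP minimising
  `E(T) = Σ ((p − T q)·n_p)²` by a linearised 6-DoF solve, and ordered
  pairwise fusion of the five views seeded by the calibrated extrinsics.
* **Meshing** — truncated signed-distance field on a regular lattice,
  marching-tetrahedra iso-surfacing, boundary-loop capping; watertight by
  construction, with the enclosed volume from the signed tetrahedron sum.
* **Validation** — Dice coefficient `2|A∩B|/(|A|+|B|)`, symmetric
  Hausdorff distance, per-vertex distance maps for heat-map rendering,
  the eight-column summary row (min/quartiles/mean/max/IQR/RMS), and
  diameter-at-height cross-section measurements.
* **Simulator** — parametric limb phantom (piecewise-linear lathe profile
  with hemispherical cap), analytic per-pixel ray casting against a green
  backdrop, range-proportional depth noise (≤2 % at 2 m), checkerboard
  corner generation, and ground-truth meshes/extrinsics for every run.

## Worked example

Simulate a five-camera capture of the default phantom and run the whole
pipeline:

```r
library(limbscan)

ws <- file.path(tempdir(), "demo")
simulate_capture(ws, seed = 1)          # renders frames, corners, ground truth
res <- run_pipeline(ws, verbose = TRUE)
#> calibrate: 5 cameras, reference radial000
#> segment radial000: 291448 pixels
#> ...
#> register: merged 31082 points
#> mesh: 97491 vertices, watertight = TRUE

res$report$dice$mean
#> [1] 0.9481335
res$report$mesh_mm$median
#> [1] 1.149887
is_watertight(res$mesh)
#> [1] TRUE
```

The Dice mean of ~0.95 says the automatic segmentation overlaps the
ground-truth silhouette almost completely (erosion deliberately trims the
rim, which the overlapping views recover); the median mesh-to-ground-truth
distance of ~1.1 mm is below the reconstruction lattice cell (~2.9 mm at
the default 128 grid), i.e. the fused surface is accurate to well under the
lattice resolution. With the camera's 2 %-at-2-m depth-noise model switched
on (`simulate_capture(..., depth_noise_sigma = 0.02)`) the median stays
around 1.5 mm.

The same flow is available from a shell via the thin wrapper
`inst/cli/limbscan`:

```sh
Rscript inst/cli/limbscan simulate --workspace ws --seed 7
Rscript inst/cli/limbscan run-all  --workspace ws --seed 7
```

Design-geometry helpers reproduce the rig's sizing chain directly:

```r
fov_extent(69.4, 230) / 2                      # 159.26 mm half-width
fov_extent(42.5, 230)                          # 178.88 mm height
resolution(fov_extent(69.4, 230), 1280)        # 0.2488 mm/px ("0.24")
standoff_distance(305, 75)                     # 230 mm
circumference_to_radius(470)$diameter_mm       # 149.6 mm
```

## Package layout

* `R/` — camera geometry, calibration, segmentation, registration,
  meshing, metrics, phantom + scene simulator, pipeline orchestration, CLI.
* `src/` — Rcpp helpers: kd-tree nearest neighbour / k-NN, 8-connected
  labelling, marching tetrahedra, CRC-32.
* `tests/testthat/` — unit and property tests per module with brute-force
  oracles, plus the end-to-end acceptance suite.
* `vignettes/limbscan-methods.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical details, limitations.
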