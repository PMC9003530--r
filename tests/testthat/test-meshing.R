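unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  # 12 triangles, outward-oriented
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),    # z = 0
    c(5, 6, 7), c(6, 8, 7),    # z = 1
    c(1, 2, 5), c(2, 6, 5),    # y = 0
    c(3, 7, 4), c(4, 7, 8),    # y = 1
    c(1, 5, 3), c(3, 5, 7),    # x = 0
    c(2, 4, 6), c(4, 8, 6))    # x = 1
  triangle_mesh(v, f)
}

sphere_surface <- function(n = 10000, r = 50, seed = 4) {
  set.seed(seed)
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  point_cloud(r * v, normals = v)
}

test_that("triangle mesh invariants are enforced", {
  expect_error(triangle_mesh(diag(3), rbind(c(1, 2, 4))),
               class = "limbscan_invalid_argument")
  expect_error(triangle_mesh(diag(3), rbind(c(1, 1, 2))),
               class = "limbscan_invalid_argument")
  cube <- unit_cube_mesh()
  expect_true(is_watertight(cube))
  open_cube <- triangle_mesh(cube$vertices, cube$faces[-1, ])
  expect_false(is_watertight(open_cube))
})

test_that("mesh volume is the orientation-corrected tetrahedron sum", {
  cube <- unit_cube_mesh()
  expect_equal(mesh_volume(cube), 1)

  stretched <- cube
  stretched$vertices[stretched$vertices[, 3] > 0, 3] <- 3
  expect_equal(mesh_volume(triangle_mesh(stretched$vertices, stretched$faces)), 3)

  expect_error(mesh_volume(triangle_mesh(cube$vertices, cube$faces[-1, ])),
               class = "limbscan_invalid_input")
})

test_that("implicit reconstruction recovers an analytic sphere", {
  mesh <- reconstruct_surface(sphere_surface(), grid_resolution = 96,
                              bandwidth_mm = 8)
  radii <- sqrt(rowSums(mesh$vertices^2))
  expect_true(all(abs(radii - 50) < 1.5))
  expect_true(is_watertight(mesh))
  # closed genus-0 surface: V - E + F = 2
  euler <- nrow(mesh$vertices) - length(unique(mesh_edge_keys_test(mesh))) +
    nrow(mesh$faces)
  expect_equal(euler, 2)
  expect_equal(mesh_volume(mesh) / (4 / 3 * pi * 50^3), 1, tolerance = 0.05)
  # vertices lie within the truncation band of an input point
  d <- nearest_distances(mesh$vertices, sphere_surface()$points)
  expect_true(all(d <= 8))
  expect_error(reconstruct_surface(point_cloud(diag(3), normals = diag(3))),
               class = "limbscan_insufficient_input")
})

test_that("reconstruction is rigid-motion equivariant", {
  cloud <- sphere_surface(4000, 40)
  tr <- rigid_transform(rotation_about(c(1, 1, 1), 0.8), c(20, -10, 5))
  m1 <- reconstruct_surface(cloud, 64, 8)
  m2 <- reconstruct_surface(apply_transform(cloud, tr), 64, 8)
  back <- transform_points(invert_transform(tr), m2$vertices)
  expect_lt(hausdorff(back, m1$vertices), attr(m1, "cell_mm"))
})

test_that("phantom reconstruction stays within a cell of the ground truth", {
  ph <- limb_phantom()
  gt <- ground_truth_mesh(ph, 128, 2)
  cloud <- phantom_surface_sample(ph, 2)   # full closed surface, exact normals
  mesh <- reconstruct_surface(cloud, 96, 6)
  expect_true(is_watertight(mesh))
  d <- c(nearest_distances(mesh$vertices, gt$vertices),
         nearest_distances(gt$vertices, mesh$vertices))
  expect_lt(median(d), attr(mesh, "cell_mm"))
  # convex regime: a single connected watertight shell even without pruning
  raw <- reconstruct_surface(cloud, 96, 6, keep_largest_component = FALSE)
  expect_true(is_watertight(raw))

  # a view-fused cloud misses the unseen base; capping closes the bottom,
  # the flat base the pipeline creates where the mold meets the table
  open_cloud <- voxel_downsample(point_cloud(gt$vertices), 2)
  open_cloud <- estimate_normals(open_cloud, k = 16,
                                 viewpoint = centroid(open_cloud$points),
                                 orient = "away")
  m2 <- close_mesh(reconstruct_surface(open_cloud, 64, 6))
  expect_true(is_watertight(m2))
})

test_that("close_mesh caps boundary loops and is idempotent", {
  cube <- unit_cube_mesh()
  expect_identical(close_mesh(cube), cube)

  # hemisphere with one circular boundary
  n <- 48; nphi <- 24
  theta <- 2 * pi * (seq_len(n) - 1) / n
  phi <- seq(0, pi / 2 - pi / (2 * nphi), length.out = nphi)
  V <- do.call(rbind, lapply(phi, function(p)
    cbind(50 * cos(p) * cos(theta), 50 * cos(p) * sin(theta), 50 * sin(p))))
  V <- rbind(V, c(0, 0, 50))
  jn <- seq_len(n); jp <- c(2:n, 1L)
  F <- matrix(0L, 0, 3)
  for (i in seq_len(nphi - 1)) {
    a <- (i - 1) * n; b <- i * n
    F <- rbind(F, cbind(a + jn, a + jp, b + jp), cbind(a + jn, b + jp, b + jn))
  }
  a <- (nphi - 1) * n
  F <- rbind(F, cbind(a + jn, a + jp, nrow(V)))
  hemi <- triangle_mesh(V, F)
  expect_false(is_watertight(hemi))
  closed <- close_mesh(hemi)
  expect_true(is_watertight(closed))
  expect_equal(nrow(closed$vertices), nrow(V) + 1)  # one centroid per loop
  # flat cap at z = 0: volume = half ball
  expect_equal(mesh_volume(closed) / (2 / 3 * pi * 50^3), 1, tolerance = 0.1)
  expect_identical(close_mesh(closed), closed)

  # open cylinder: two boundary loops, exactly V + 2 vertices
  zc <- rbind(cbind(20 * cos(theta), 20 * sin(theta), 0),
              cbind(20 * cos(theta), 20 * sin(theta), 40))
  Fc <- rbind(cbind(jn, jp, n + jp), cbind(jn, n + jp, n + jn))
  cyl <- close_mesh(triangle_mesh(zc, Fc))
  expect_true(is_watertight(cyl))
  expect_equal(nrow(cyl$vertices), 2 * n + 2)
  expect_equal(mesh_volume(cyl) / (pi * 20^2 * 40), 1, tolerance = 0.02)
})
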