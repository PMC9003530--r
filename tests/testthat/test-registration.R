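sphere_cloud <- function(n, r = 50, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  point_cloud(r * v)
}

test_that("apply_transform moves points and normals, preserves colors", {
  pc <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0)),
                    colors = rbind(c(1, 0, 0), c(0, 1, 0)),
                    normals = rbind(c(0, 0, 1), c(1, 0, 0)))
  expect_equal(apply_transform(pc, rigid_transform()), pc)

  tr <- rigid_transform(diag(3), c(1, 2, 3))
  expect_equal(apply_transform(pc, tr)$points[1, ], c(1, 2, 3))

  set.seed(17)
  t1 <- rigid_transform(random_rotation(), rnorm(3))
  t2 <- rigid_transform(random_rotation(), rnorm(3))
  lhs <- apply_transform(apply_transform(pc, t1), t2)
  rhs <- apply_transform(pc, compose_transform(t2, t1))
  expect_equal(lhs$points, rhs$points, tolerance = 1e-9)
  expect_equal(lhs$normals, rhs$normals, tolerance = 1e-9)
  expect_equal(lhs$colors, pc$colors)
})

test_that("voxel downsampling buckets points like the brute-force oracle", {
  one <- point_cloud(matrix(runif(30, 0, 1.9), 10, 3))
  expect_equal(nrow(voxel_downsample(one, 2)$points), 1)
  expect_equal(voxel_downsample(one, 2)$points[1, ], centroid(one$points))

  grid <- as.matrix(expand.grid(x = seq(0, 90, 10), y = seq(0, 90, 10), z = 0))
  pc <- point_cloud(grid + 0.5)
  expect_equal(nrow(voxel_downsample(pc, 2)$points), nrow(grid))

  set.seed(41)
  for (i in 1:5) {
    pts <- matrix(runif(3000, -40, 40), 1000, 3)
    vox <- runif(1, 2, 12)
    expect_equal(nrow(voxel_downsample(point_cloud(pts), vox)$points),
                 naive_voxel_count(pts, vox))
  }

  # idempotence in point count at a fixed size
  d1 <- voxel_downsample(point_cloud(matrix(runif(900, 0, 50), 300, 3)), 5)
  d2 <- voxel_downsample(d1, 5)
  expect_equal(nrow(d2$points), nrow(d1$points))
})

test_that("normal estimation recovers plane and sphere normals", {
  set.seed(2)
  plane <- point_cloud(cbind(runif(200, -50, 50), runif(200, -50, 50), 0))
  n <- estimate_normals(plane, k = 10, viewpoint = c(0, 0, 100))
  expect_true(all(abs(n$normals[, 3] - 1) < 1e-6))

  sph <- sphere_cloud(10000)
  n2 <- estimate_normals(sph, k = 12, viewpoint = c(0, 0, 0))
  radial <- -sph$points / 50            # inward, toward the centre viewpoint
  ang <- acos(pmin(1, abs(rowSums(n2$normals * radial))))
  expect_lt(max(ang) * 180 / pi, 5)
  # and all point inward toward the viewpoint at the centre
  expect_true(all(rowSums(n2$normals * sph$points) < 0))

  four <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)))
  n3 <- estimate_normals(four, k = 3, viewpoint = c(0, 0, 1))
  expect_equal(abs(n3$normals[, 3]), rep(1, 4), tolerance = 1e-9)
  expect_error(estimate_normals(four, k = 4),
               class = "limbscan_invalid_argument")
})

test_that("point-to-plane ICP satisfies its objective contract", {
  # single correspondence, identity transform: E = ((p - q) . n)^2 = 1
  tgt <- point_cloud(rbind(c(0, 0, 1), c(50, 0, 1), c(0, 50, 1)),
                     normals = rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1)))
  src <- point_cloud(matrix(c(0, 0, 0), 1))
  st <- limbscan:::p2plane_state(src$points, tgt$points, tgt$normals,
                                 rigid_transform(), 10)
  expect_equal(st$E, 1)

  # source = target converges to identity with E ~ 0
  ph <- limb_phantom()
  surf <- voxel_downsample(point_cloud(ground_truth_mesh(ph, 96, 2)$vertices), 2)
  tgt2 <- estimate_normals(surf, k = 16, viewpoint = centroid(surf$points),
                           orient = "away")
  res0 <- icp_point_to_plane(surf, tgt2)
  expect_equal(res0$transform$rotation, diag(3), tolerance = 1e-9)
  expect_lt(res0$objective, 1e-12)

  # strict pose recovery needs an asymmetric target: a plane-plus-bumps
  # surface sample (a revolved phantom leaves its axial rotation free)
  set.seed(54)
  g <- as.matrix(expand.grid(x = seq(-60, 60, 1.5), y = seq(-60, 60, 1.5)))
  z <- 4 * sin(g[, 1] / 9) * cos(g[, 2] / 7) + 2 * sin(g[, 1] / 23 + 1)
  bump <- point_cloud(cbind(g, z))
  bump_t <- estimate_normals(bump, k = 12, viewpoint = c(0, 0, 1e5))
  Tp <- rigid_transform(rotation_about(c(0, 0, 1), 2 * pi / 180), c(2, -2, 1))
  res <- icp_point_to_plane(apply_transform(bump, Tp), bump_t)
  err <- compose_transform(res$transform, Tp)
  expect_lt(rotation_angle(err$rotation) * 180 / pi, 0.1)
  expect_lt(sqrt(sum(err$translation^2)), 0.2)

  # monotone refinement: objective at the result <= objective at init
  init_state <- limbscan:::p2plane_state(
    apply_transform(bump, Tp)$points, bump_t$points, bump_t$normals,
    rigid_transform(), 10)
  expect_lte(res$objective, init_state$E)

  # convergence basin on the phantom: perturbed copies return onto the
  # surface (pose modulo the axial symmetry)
  set.seed(55)
  for (i in 1:3) {
    Tb <- rigid_transform(rotation_about(rnorm(3), runif(1, 0, 5) * pi / 180),
                          runif(3, -5, 5))
    rb <- icp_point_to_plane(apply_transform(surf, Tb), tgt2)
    back <- transform_points(rb$transform,
                             transform_points(Tb, surf$points))
    expect_lt(median(nearest_distances(back, surf$points)), 0.5)
  }

  far <- apply_transform(surf, rigid_transform(diag(3), c(1e5, 0, 0)))
  expect_error(icp_point_to_plane(far, tgt2), class = "limbscan_no_overlap")
})

test_that("ordered pairwise registration fuses the simulated views", {
  layout <- small_layout()
  rig <- make_rig(layout)
  ph <- limb_phantom()
  ref_from_world <- invert_transform(rig[[1]])
  clouds <- lapply(rig, function(pose) {
    r <- render_rgbd(ph, pose, layout$intrinsics)
    deproject(r$frame, r$silhouette)
  })
  extr <- lapply(rig, function(p) compose_transform(ref_from_world, p))

  # perfectly aligned by extrinsics: the fused cloud stays on the surface
  # (refinements may slide along the phantom's symmetry directions)
  gt_ref0 <- transform_points(ref_from_world,
                              ground_truth_mesh(ph, 128, 2)$vertices)
  merged <- pairwise_register(clouds, extr, icp_params())
  expect_lt(median(nearest_distances(merged$points, gt_ref0)), 1)

  # perturbed extrinsics (1 degree / 2 mm): ICP reduces each view's RMSD
  # to the ground-truth surface
  set.seed(77)
  gt_ref <- transform_points(ref_from_world,
                             ground_truth_mesh(ph, 128, 2)$vertices)
  perturbed <- lapply(seq_along(extr), function(i) {
    if (i == 1) return(extr[[i]])
    compose_transform(extr[[i]],
                      rigid_transform(rotation_about(rnorm(3), pi / 180),
                                      runif(3, -2, 2)))
  })
  pre <- lapply(seq_along(clouds), function(i)
    voxel_downsample(apply_transform(clouds[[i]], perturbed[[i]]), 2))
  merged2 <- pairwise_register(clouds, perturbed, icp_params())
  refs2 <- attr(merged2, "refinements")
  for (i in seq_along(clouds)[-1]) {
    post_pts <- transform_points(refs2[[i]]$transform, pre[[i]]$points)
    rms_pre <- sqrt(mean(nearest_distances(pre[[i]]$points, gt_ref)^2))
    rms_post <- sqrt(mean(nearest_distances(post_pts, gt_ref)^2))
    expect_lt(rms_post, rms_pre)
  }

  # zero-overlap views are reported with the failing pair
  off <- apply_transform(clouds[[2]], rigid_transform(diag(3), c(0, 0, 1e5)))
  expect_error(
    pairwise_register(list(clouds[[1]], off),
                      list(extr[[1]], rigid_transform()), icp_params()),
    class = "limbscan_no_overlap")
})

test_that("pairwise registration is invariant under a global rigid motion", {
  layout <- small_layout()
  rig <- make_rig(layout)[1:3]
  ph <- limb_phantom()
  clouds <- lapply(rig, function(pose) {
    r <- render_rgbd(ph, pose, layout$intrinsics)
    voxel_downsample(deproject(r$frame, r$silhouette), 4)
  })
  ref_from_world <- invert_transform(rig[[1]])
  extr <- lapply(rig, function(p) compose_transform(ref_from_world, p))
  move <- rigid_transform(rotation_about(c(1, 2, 3), 0.5), c(40, -30, 60))
  extr_moved <- lapply(extr, function(e) compose_transform(move, e))

  m1 <- pairwise_register(clouds, extr, icp_params(voxel_size_mm = 4))
  m2 <- pairwise_register(clouds, extr_moved, icp_params(voxel_size_mm = 4))
  back <- transform_points(invert_transform(move), m2$points)
  expect_lt(hausdorff(back, m1$points), 4)
})
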