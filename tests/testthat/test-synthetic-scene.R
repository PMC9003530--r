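test_that("rig poses sit on the frame circle with inward optical axes", {
  rig <- make_rig()
  expect_length(rig, 5)
  expect_named(rig, c("radial000", "radial090", "radial180", "radial270",
                      "endview"))
  # consecutive radial poses related by exactly 90 degrees about the axis
  Rz <- rotation_about(c(0, 0, 1), pi / 2)
  for (i in 1:3) {
    a <- rig[[i]]; b <- rig[[i + 1]]
    expect_equal(Rz %*% a$rotation, b$rotation, tolerance = 1e-12)
    expect_equal(as.numeric(Rz %*% a$translation), b$translation,
                 tolerance = 1e-9)
  }
  expect_equal(rig[["radial000"]]$translation[1:2], c(305, 0))
  expect_equal(rig[["radial180"]]$translation[1:2], c(-305, 0))

  # every optical axis passes through the rig axis
  for (p in rig[1:4]) {
    pos <- p$translation
    dir <- p$rotation[, 3]
    # distance from the z axis to the line pos + t dir, in the xy plane
    t_star <- -sum(pos[1:2] * dir[1:2]) / sum(dir[1:2]^2)
    expect_lt(sqrt(sum((pos[1:2] + t_star * dir[1:2])^2)), 1e-9)
    expect_equal(det(p$rotation), 1, tolerance = 1e-12)
  }
  expect_equal(rig[["endview"]]$rotation[, 3], c(0, 0, -1))
})

test_that("rendered depth equals the analytic ray intersection", {
  ph <- limb_phantom()
  layout <- small_layout()
  rig <- make_rig(layout)
  r <- render_rgbd(ph, rig[["radial000"]], layout$intrinsics)

  # centre pixel: standoff = frame radius - profile radius at ring height
  centre <- r$frame$depth[91, 161]
  expect_equal(centre, 305 - phantom_radius(ph, 125), tolerance = 1e-6)

  # spot-check random silhouette pixels against a fresh analytic cast
  set.seed(8)
  idx <- sample(which(r$silhouette), 50)
  K <- layout$intrinsics
  v <- (idx - 1) %% 180; u <- (idx - 1) %/% 180
  dir_cam <- cbind((u - K$cx) / K$fx, (v - K$cy) / K$fy, 1)
  dirs <- dir_cam %*% t(rig[["radial000"]]$rotation)
  t_ref <- limbscan:::ray_cast_phantom(ph, matrix(rig[["radial000"]]$translation, 1), dirs)
  expect_equal(r$frame$depth[idx], t_ref, tolerance = 1e-6)

  # deprojected silhouette points lie on the phantom surface
  pc <- deproject(r$frame, r$silhouette)
  world <- transform_points(rig[["radial000"]], pc$points)
  shaft <- world[, 3] >= 0 & world[, 3] <= ph$cap_center_z
  rr <- sqrt(rowSums(world[shaft, 1:2]^2))
  expect_lt(max(abs(rr - phantom_radius(ph, world[shaft, 3]))), 1e-6)

  # backdrop pixels are green at the backdrop distance
  bg <- which(!r$silhouette)[1]
  expect_equal(r$frame$depth[bg], ph$backdrop_mm)
  expect_equal(r$frame$color[, , 2][bg], ph$backdrop_color[2])
})

test_that("a broadside cylinder silhouette has the projected width", {
  # constant-radius phantom seen broadside: silhouette width in pixels
  # matches 2r scaled by depth at the silhouette edge
  ph <- limb_phantom(profile_heights = c(0, 200), profile_radii = c(50, 50))
  layout <- small_layout()
  r <- render_rgbd(ph, make_rig(layout)[["radial000"]], layout$intrinsics)
  K <- layout$intrinsics
  # rows = the narrow (v) axis, which looks across the cylinder
  mid_col <- 161  # u column imaging z ~ axial_position
  sil_rows <- which(r$silhouette[, mid_col])
  width_px <- max(sil_rows) - min(sil_rows) + 1
  # the silhouette edge ray is tangent: range = sqrt(l^2 - r^2) to the
  # tangent point at distance sqrt(305^2 - 50^2)
  tangent_half_angle <- asin(50 / 305)
  expected_px <- 2 * tan(tangent_half_angle) * K$fy
  expect_lt(abs(width_px - expected_px), 2)
})

test_that("depth noise follows the range-proportional accuracy model", {
  K <- camera_intrinsics(400, 250, 100, 100, 200, 125)
  d <- matrix(2000, 250, 400)
  f <- rgbd_frame(array(0, c(250, 400, 3)), d, K)
  expect_identical(add_depth_noise(f, 0), f)

  noisy <- add_depth_noise(f, 0.02, seed = 99)
  sd_hat <- stats::sd(noisy$depth - 2000)
  expect_equal(sd_hat, 40, tolerance = 0.02)       # 2% of 2 m

  again <- add_depth_noise(f, 0.02, seed = 99)
  expect_identical(noisy$depth, again$depth)
  other <- add_depth_noise(f, 0.02, seed = 100)
  expect_false(identical(noisy$depth, other$depth))

  # zero depths are left invalid
  d2 <- d; d2[1:10, 1:10] <- 0
  f2 <- rgbd_frame(array(0, c(250, 400, 3)), d2, K)
  expect_true(all(add_depth_noise(f2, 0.02, seed = 1)$depth[1:10, 1:10] == 0))
})

test_that("checkerboard corners are consistent across cameras", {
  rig <- make_rig()
  cb <- render_checkerboard(rig)
  expect_true(all(vapply(cb$corner_sets, nrow, integer(1)) == 54))

  # a camera at the board pose observes the bare board model
  board_pose <- rigid_transform(diag(3), c(-100, -62.5, 125))
  cb2 <- render_checkerboard(list(cam = board_pose), board_pose)
  expect_equal(cb2$corner_sets$cam, cb2$board_model, tolerance = 1e-9)

  # noise is seeded and reproducible
  n1 <- render_checkerboard(rig, noise_sd = 0.5, seed = 5)
  n2 <- render_checkerboard(rig, noise_sd = 0.5, seed = 5)
  expect_identical(n1, n2)

  # a board behind a camera is a visibility error
  behind <- rigid_transform(diag(3), c(0, 0, 1e5))
  expect_error(render_checkerboard(rig, behind), class = "limbscan_visibility")
})

test_that("ground-truth meshes are watertight with the analytic volume", {
  cylinder <- limb_phantom(profile_heights = c(0, 200),
                           profile_radii = c(60, 60))
  m <- ground_truth_mesh(cylinder, n_theta = 192, edge_mm = 2)
  expect_true(is_watertight(m))
  analytic <- pi * 60^2 * 200 + 2 / 3 * pi * 60^3
  expect_equal(mesh_volume(m) / analytic, 1, tolerance = 0.01)

  for (res in list(c(32, 8), c(96, 3))) {
    mm <- ground_truth_mesh(limb_phantom(), res[1], res[2])
    expect_true(is_watertight(mm))
  }
})
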