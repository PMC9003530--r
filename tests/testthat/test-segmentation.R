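make_frame <- function(depth, color_val = 128) {
  h <- nrow(depth); w <- ncol(depth)
  K <- camera_intrinsics(w, h, 100, 100, w / 2, h / 2)
  rgbd_frame(array(color_val, c(h, w, 3)), depth, K)
}

test_that("depth threshold keeps valid near pixels only", {
  f <- make_frame(matrix(c(250, 600, 0, 500), 2, 2))
  m <- depth_threshold(f, 500)
  expect_equal(as.vector(m), c(TRUE, FALSE, FALSE, TRUE))
  expect_false(any(depth_threshold(make_frame(matrix(0, 3, 3)), 500)))
  expect_true(all(depth_threshold(make_frame(matrix(500, 3, 3)), 500)))
})

test_that("HSV color filter removes the sheet color range", {
  green <- array(0, c(4, 4, 3)); green[, , 2] <- 200; green[, , 1] <- 40
  green[, , 3] <- 60
  expect_false(any(hsv_color_filter(green)))

  red <- array(0, c(4, 4, 3)); red[, , 1] <- 220
  expect_true(all(hsv_color_filter(red)))

  # half green, half white: mask true exactly on the white half
  # (white has zero saturation, outside the green S bound)
  mix <- green
  mix[, 3:4, 1] <- 255; mix[, 3:4, 2] <- 255; mix[, 3:4, 3] <- 255
  m <- hsv_color_filter(mix)
  expect_equal(m, cbind(matrix(FALSE, 4, 2), matrix(TRUE, 4, 2)))

  # per-pixel agreement with a direct HSV conversion oracle
  set.seed(5)
  rnd <- array(sample(0:255, 6 * 6 * 3, TRUE), c(6, 6, 3))
  m2 <- hsv_color_filter(rnd, c(70, 0.25, 0.2), c(170, 1, 1))
  for (i in 1:6) for (j in 1:6) {
    hsv <- grDevices::rgb2hsv(rnd[i, j, 1], rnd[i, j, 2], rnd[i, j, 3],
                              maxColorValue = 255)
    inside <- hsv[1] * 360 >= 70 && hsv[1] * 360 <= 170 &&
      hsv[2] >= 0.25 && hsv[3] >= 0.2
    expect_identical(m2[i, j], !inside)
  }
  expect_error(hsv_color_filter(rnd, c(70, 0.5, 0), c(170, 0.2, 1)),
               class = "limbscan_invalid_argument")
})

test_that("otsu threshold equals exhaustive search on random rasters", {
  expect_error(otsu_threshold(matrix(7, 3, 3)),
               class = "limbscan_degenerate_input")
  th <- otsu_threshold(c(rep(10, 60), rep(240, 40)))
  expect_gt(th, 10); expect_lt(th, 240)

  set.seed(9)
  for (i in 1:10) {
    g <- matrix(sample(0:255, 400, TRUE, prob = runif(256)^2), 20, 20)
    if (length(unique(as.vector(g))) < 2) next
    expect_identical(otsu_threshold(g), naive_otsu(g))
  }
})

test_that("otsu separates two Gaussian intensity populations", {
  set.seed(123)
  lo <- pmin(pmax(round(rnorm(1000, 60, 10)), 0), 255)
  hi <- pmin(pmax(round(rnorm(1000, 200, 10)), 0), 255)
  th <- otsu_threshold(c(lo, hi))
  miss <- (sum(lo > th) + sum(hi <= th)) / 2000
  expect_lt(miss, 0.01)
})

test_that("largest region keeps the biggest 8-connected component", {
  single <- matrix(FALSE, 8, 8); single[2:4, 2:4] <- TRUE
  expect_equal(largest_region(single), single)

  two <- matrix(FALSE, 8, 8)
  two[1, 1:5] <- TRUE            # 5 px
  two[7, 6:8] <- TRUE            # 3 px
  expect_equal(largest_region(two), two & (row(two) == 1))

  # equal blobs: earliest first pixel in row-major scan order wins
  eq <- matrix(FALSE, 8, 8)
  eq[5, 1:3] <- TRUE             # starts at scan position (5,1)
  eq[2, 5:7] <- TRUE             # starts at scan position (2,5) -> earlier row
  expect_equal(largest_region(eq), eq & (row(eq) == 2))

  # diagonal touch is connected under 8-connectivity
  diag8 <- matrix(FALSE, 4, 4); diag8[1, 1] <- diag8[2, 2] <- TRUE
  expect_equal(sum(largest_region(diag8)), 2)

  expect_error(largest_region(matrix(FALSE, 3, 3)),
               class = "limbscan_empty_segmentation")
})

test_that("median filter matches the naive sliding-window oracle", {
  const <- matrix(TRUE, 6, 6)
  expect_equal(median_filter(const, 3, 5), const)

  lone <- matrix(FALSE, 20, 20); lone[10, 10] <- TRUE
  expect_false(any(median_filter(lone, 15, 1)))

  set.seed(31)
  for (i in 1:5) {
    m <- matrix(runif(32 * 32) > 0.5, 32, 32)
    expect_equal(median_filter(m, 3, 1), naive_median_pass(m, 3))
  }
  expect_error(median_filter(const, 4, 1), class = "limbscan_invalid_argument")
})

test_that("erosion matches the naive window-minimum oracle and shrinks", {
  expect_false(any(erode(matrix(FALSE, 10, 10), 3, 1)))

  # solid 30x30 square, 3x3 element, 10 passes -> centred 10x10 square
  sq <- matrix(FALSE, 40, 40); sq[6:35, 6:35] <- TRUE
  e <- erode(sq, 3, 10)
  expect_equal(sum(e), 100)
  expect_true(all(e[16:25, 16:25]))

  set.seed(32)
  for (i in 1:5) {
    m <- matrix(runif(24 * 24) > 0.4, 24, 24)
    one <- erode(m, 3, 1)
    expect_equal(one, naive_erode_pass(m, 3))
    expect_true(all(m[one]))         # erode(mask) is a subset of mask
    # iterating is monotonically non-increasing in pixel count
    counts <- sapply(0:4, function(it) sum(erode(m, 3, it)))
    expect_true(all(diff(counts) <= 0))
  }
  expect_error(erode(sq, 2, 1), class = "limbscan_invalid_argument")
})

test_that("the segmentation chain isolates the phantom silhouette", {
  ph <- limb_phantom()
  layout <- rig_layout()
  rig <- make_rig(layout)
  r <- render_rgbd(ph, rig[["radial000"]], layout$intrinsics)
  seg <- segment(r$frame, keep_stages = TRUE)
  expect_gte(dice(seg$mask, r$silhouette), 0.95)
  # the final mask never includes a pixel rejected by the depth threshold
  expect_true(all(seg$stages$depth[seg$mask]))
  expect_true(all(seg$stages$support[seg$mask]))

  # a small spurious non-green blob is dropped by region selection
  tampered <- r$frame$color
  tampered[1:20, 1:20, 1] <- 200; tampered[1:20, 1:20, 2] <- 30
  tampered[1:20, 1:20, 3] <- 30
  d2 <- r$frame$depth; d2[1:20, 1:20] <- 300
  seg2 <- segment(rgbd_frame(tampered, d2, r$frame$intrinsics))
  expect_false(any(seg2$mask[1:20, 1:20]))

  # an all-backdrop frame fails with a stage-named error
  flat <- rgbd_frame(array(rep(c(60, 179, 75), each = 180 * 320),
                           c(180, 320, 3)),
                     matrix(600, 180, 320), small_intrinsics())
  err <- tryCatch(segment(flat), condition = identity)
  expect_s3_class(err, "limbscan_empty_segmentation")
  expect_match(conditionMessage(err), "depth_threshold")
})

test_that("a seed pixel overrides the automatic region choice", {
  K <- camera_intrinsics(30, 30, 10, 10, 15, 15)
  color <- array(0, c(30, 30, 3))
  color[5:8, 5:8, ] <- 200        # small bright blob
  color[15:28, 10:25, ] <- 180    # large bright blob
  depth <- matrix(0, 30, 30)
  depth[5:8, 5:8] <- 300
  depth[15:28, 10:25] <- 300
  f <- rgbd_frame(color, depth, K)
  cfg <- segmentation_config(median_iters = 0, erosion_iters = 0)
  auto <- segment(f, cfg)
  expect_true(auto$mask[20, 20] && !auto$mask[6, 6])
  manual <- segment(f, cfg, seed_pixel = c(6, 6))
  expect_true(manual$mask[6, 6] && !manual$mask[20, 20])
})
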