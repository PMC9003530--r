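#' Segmentation configuration
#'
#' Parameters of the segmentation chain: background depth cut, green-sheet
#' HSV removal, Otsu binarisation with largest-region extraction, median
#' smoothing and erosion. Defaults follow the scanning setup the pipeline
#' is designed around: a 500 mm depth cut separating the target from the
#' backdrop, removal of any green hue, a 15 x 15 median mask applied 10
#' times, and a 3 x 3 erosion applied 10 times.
#'
#' HSV bounds use H in `[0, 360)`, S and V in `[0, 1]`. The default range
#' H in `[70, 170]`, S >= 0.25, V >= 0.2 covers dark-to-bright greens.
#'
#' @param depth_max_mm background depth threshold (mm).
#' @param hsv_lower,hsv_upper 3-vectors bounding the removed (sheet) color.
#' @param median_size,median_iters odd window size and pass count of the
#'   median smoothing.
#' @param erosion_size,erosion_iters odd window size and pass count of the
#'   erosion.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(depth_max_mm = 500,
                                hsv_lower = c(70, 0.25, 0.2),
                                hsv_upper = c(170, 1, 1),
                                median_size = 15, median_iters = 10,
                                erosion_size = 3, erosion_iters = 10) {
  check_that(depth_max_mm > 0, "depth_max_mm must be positive")
  check_that(median_size %% 2 == 1 && median_size >= 1, "median_size must be odd")
  check_that(erosion_size %% 2 == 1 && erosion_size >= 1, "erosion_size must be odd")
  check_that(median_iters >= 0 && erosion_iters >= 0,
             "iteration counts must be non-negative")
  check_that(length(hsv_lower) == 3 && length(hsv_upper) == 3,
             "HSV bounds must be 3-vectors")
  check_that(all(hsv_lower[2:3] <= hsv_upper[2:3]),
             "saturation/value bounds must satisfy lower <= upper")
  structure(list(depth_max_mm = depth_max_mm,
                 hsv_lower = as.numeric(hsv_lower),
                 hsv_upper = as.numeric(hsv_upper),
                 median_size = as.integer(median_size),
                 median_iters = as.integer(median_iters),
                 erosion_size = as.integer(erosion_size),
                 erosion_iters = as.integer(erosion_iters)),
            class = "segmentation_config")
}

#' Background removal by depth threshold
#'
#' @param frame An [rgbd_frame()].
#' @param depth_max_mm cut-off in millimetres (inclusive).
#' @return Logical H x W mask, true where `0 < depth <= depth_max_mm`.
#' @export
depth_threshold <- function(frame, depth_max_mm = 500) {
  stopifnot(inherits(frame, "rgbd_frame"))
  d <- frame$depth * frame$intrinsics$depth_scale
  d > 0 & d <= depth_max_mm
}

#' Remove a color range in HSV space
#'
#' Converts the raster to HSV and masks out pixels whose hue, saturation
#' and value all fall inside `[lower, upper]` (the sheet color); the
#' returned mask is true for pixels *outside* the range. The hue interval
#' may wrap around 360 (lower hue greater than upper hue).
#'
#' @param color H x W x 3 array, 8-bit per channel.
#' @param hsv_lower,hsv_upper 3-vectors (H in degrees, S and V in `[0, 1]`).
#' @return Logical H x W mask of pixels outside the color range.
#' @export
hsv_color_filter <- function(color, hsv_lower = c(70, 0.25, 0.2),
                             hsv_upper = c(170, 1, 1)) {
  check_that(length(dim(color)) == 3 && dim(color)[3] == 3,
             "color must be an H x W x 3 array")
  check_that(length(hsv_lower) == 3 && length(hsv_upper) == 3,
             "HSV bounds must be 3-vectors")
  check_that(all(hsv_lower[2:3] <= hsv_upper[2:3]) &&
             all(c(hsv_lower[2:3], hsv_upper[2:3]) >= 0) &&
             all(c(hsv_lower[2:3], hsv_upper[2:3]) <= 1),
             "malformed saturation/value bounds")
  hsv <- grDevices::rgb2hsv(r = as.vector(color[, , 1]),
                            g = as.vector(color[, , 2]),
                            b = as.vector(color[, , 3]), maxColorValue = 255)
  hue <- hsv[1, ] * 360
  if (hsv_lower[1] <= hsv_upper[1]) {
    in_h <- hue >= hsv_lower[1] & hue <= hsv_upper[1]
  } else {  # wrap-around interval, e.g. reds spanning 350..10
    in_h <- hue >= hsv_lower[1] | hue <= hsv_upper[1]
  }
  inside <- in_h &
    hsv[2, ] >= hsv_lower[2] & hsv[2, ] <= hsv_upper[2] &
    hsv[3, ] >= hsv_lower[3] & hsv[3, ] <= hsv_upper[3]
  matrix(!inside, nrow = dim(color)[1], ncol = dim(color)[2])
}

#' Otsu's threshold
#'
#' Histogram threshold minimising the within-class intensity variance
#' (equivalently maximising the between-class variance) over a 256-bin
#' histogram of 8-bit intensities. Binarisation uses `value > threshold`.
#' When several thresholds maximise the criterion (a flat run between two
#' well-separated modes), the midpoint of the maximising run is returned.
#'
#' @param gray numeric matrix or vector of intensities in `[0, 255]`.
#' @return The selected threshold (an integer in 0..254).
#' @export
otsu_threshold <- function(gray) {
  g <- as.integer(round(as.vector(gray)))
  check_that(all(g >= 0 & g <= 255), "intensities must lie in [0, 255]")
  if (length(unique(g)) < 2)
    ls_stop("constant raster has no Otsu threshold", "degenerate_input")
  counts <- tabulate(g + 1L, nbins = 256L)
  n <- sum(counts)
  levels <- 0:255
  w0 <- cumsum(counts)[1:255]                     # class 0: value <= th
  w1 <- n - w0
  s0 <- cumsum(counts * levels)[1:255]
  m0 <- ifelse(w0 > 0, s0 / w0, 0)
  m1 <- ifelse(w1 > 0, (sum(counts * levels) - s0) / w1, 0)
  between <- w0 / n * w1 / n * (m0 - m1)^2
  between[w0 == 0 | w1 == 0] <- -Inf
  best <- which(between == max(between))
  as.integer(floor((min(best) + max(best)) / 2)) - 1L
}

#' Keep the largest connected region of a binary mask
#'
#' 8-connectivity; ties between equally sized regions are broken toward
#' the region whose first pixel comes earliest in row-major (reading)
#' scan order.
#'
#' @param mask logical H x W matrix.
#' @return Logical mask retaining exactly one connected component.
#' @export
largest_region <- function(mask) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!any(mask)) ls_stop("mask is empty: nothing to segment", "empty_segmentation")
  lab <- .cpp_label_components(mask)
  counts <- tabulate(lab[lab > 0])
  best <- which(counts == max(counts))
  if (length(best) > 1) {
    # row-major scan position of each candidate's first pixel
    h <- nrow(mask); w <- ncol(mask)
    pos <- vapply(best, function(l) {
      idx <- which(lab == l)                 # column-major indices
      r <- (idx - 1) %% h
      c <- (idx - 1) %/% h
      min(r * w + c)
    }, numeric(1))
    best <- best[which.min(pos)]
  }
  lab == best[1]
}

# Sliding-window sums over `size x size` neighbourhoods via a summed-area
# table of the padded image; pad supplies the border policy.
window_sums <- function(padded, size, h, w) {
  sat <- apply(apply(padded, 2, cumsum), 1, cumsum)  # transposed SAT
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  i0 <- 1:h; j0 <- 1:w
  sat[i0 + size, j0 + size, drop = FALSE] -
    sat[i0, j0 + size, drop = FALSE] -
    sat[i0 + size, j0, drop = FALSE] +
    sat[i0, j0, drop = FALSE]
}

pad_reflect <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  check_that(r < h && r < w, "window larger than the image")
  ri <- c(rev(seq_len(r) + 1), seq_len(h), h - seq_len(r))
  ci <- c(rev(seq_len(r) + 1), seq_len(w), w - seq_len(r))
  m[ri, ci, drop = FALSE]
}

pad_zero <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h + 2 * r, w + 2 * r)
  out[r + seq_len(h), r + seq_len(w)] <- m
  out
}

#' Median smoothing of a binary mask
#'
#' Each pass replaces every pixel by the median of its `size x size`
#' window (reflect padding at the borders); for a binary mask this is a
#' majority vote, and the odd window count rules out ties.
#'
#' @param mask logical H x W matrix.
#' @param size odd window edge length.
#' @param iterations number of passes.
#' @return Smoothed logical mask.
#' @export
median_filter <- function(mask, size = 15, iterations = 10) {
  check_that(size %% 2 == 1, "window size must be odd")
  check_that(iterations >= 0, "iterations must be non-negative")
  mask <- as.matrix(mask)
  storage.mode(mask) <- "double"
  h <- nrow(mask); w <- ncol(mask)
  r <- (size - 1) / 2
  half <- size^2 / 2
  for (i in seq_len(iterations)) {
    mask[] <- as.double(window_sums(pad_reflect(mask, r), size, h, w) > half)
  }
  mask > 0
}

#' Binary erosion
#'
#' Each pass keeps a pixel only if its whole `size x size` window is true;
#' pixels outside the image count as false, so every pass strips the image
#' border.
#'
#' @inheritParams median_filter
#' @return Eroded logical mask.
#' @export
erode <- function(mask, size = 3, iterations = 10) {
  check_that(size %% 2 == 1, "window size must be odd")
  check_that(iterations >= 0, "iterations must be non-negative")
  mask <- as.matrix(mask)
  storage.mode(mask) <- "double"
  h <- nrow(mask); w <- ncol(mask)
  r <- (size - 1) / 2
  full <- size^2
  for (i in seq_len(iterations)) {
    mask[] <- as.double(window_sums(pad_zero(mask, r), size, h, w) >= full - 0.5)
  }
  mask > 0
}

#' Segment the target object in an RGB-D frame
#'
#' Applies, in order: depth threshold AND HSV color removal; Otsu
#' binarisation of the grayscale (luma) image restricted to that support;
#' largest-connected-region extraction; median smoothing; erosion; and
#' finally a bit-wise application of the mask to the color raster. Any
#' stage that empties the mask raises an `empty_segmentation` error naming
#' the stage; `seed_pixel` overrides the largest-region choice when the
#' automatic selection picks the wrong component (the manual-intervention
#' path).
#'
#' @param frame An [rgbd_frame()].
#' @param config A [segmentation_config()].
#' @param seed_pixel optional `c(row, col)` (1-based) forcing the connected
#'   region containing that pixel to be selected instead of the largest.
#' @param keep_stages if true, attach every intermediate mask for debugging.
#' @return List with `mask` (logical H x W), `masked_color` (H x W x 3 with
#'   non-mask pixels zeroed), and, when `keep_stages`, a `stages` list.
#' @export
segment <- function(frame, config = segmentation_config(), seed_pixel = NULL,
                    keep_stages = FALSE) {
  stopifnot(inherits(frame, "rgbd_frame"), inherits(config, "segmentation_config"))
  fail <- function(stage)
    ls_stop(sprintf("segmentation produced an empty mask at stage '%s'", stage),
            "empty_segmentation")

  m_depth <- depth_threshold(frame, config$depth_max_mm)
  if (!any(m_depth)) fail("depth_threshold")
  m_color <- hsv_color_filter(frame$color, config$hsv_lower, config$hsv_upper)
  support <- m_depth & m_color
  if (!any(support)) fail("color_filter")

  # Otsu on the luma of the supported pixels; outside the support the
  # region image is zero, so `> threshold` keeps only bright target pixels.
  luma <- 0.299 * frame$color[, , 1] + 0.587 * frame$color[, , 2] +
    0.114 * frame$color[, , 3]
  region_img <- round(luma) * support
  m_otsu <- tryCatch(region_img > otsu_threshold(region_img),
                     limbscan_degenerate_input = function(e) support)
  if (!any(m_otsu)) fail("otsu")

  if (is.null(seed_pixel)) {
    m_region <- largest_region(m_otsu)
  } else {
    lab <- .cpp_label_components(m_otsu)
    l <- lab[seed_pixel[1], seed_pixel[2]]
    if (l == 0) fail("region_selection")
    m_region <- lab == l
  }
  m_median <- median_filter(m_region, config$median_size, config$median_iters)
  if (!any(m_median)) fail("median_filter")
  # median smoothing may bleed past the depth/color support; clip back so
  # the final mask never includes a pixel the depth threshold rejected
  m_median <- m_median & support
  if (!any(m_median)) fail("median_filter")
  m_final <- erode(m_median, config$erosion_size, config$erosion_iters)
  if (!any(m_final)) fail("erosion")

  masked <- frame$color
  masked[, , 1] <- masked[, , 1] * m_final
  masked[, , 2] <- masked[, , 2] * m_final
  masked[, , 3] <- masked[, , 3] * m_final
  out <- list(mask = m_final, masked_color = masked)
  if (keep_stages)
    out$stages <- list(depth = m_depth, color = m_color, support = support,
                       otsu = m_otsu, region = m_region, median = m_median)
  out
}
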