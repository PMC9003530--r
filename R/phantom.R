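#' Parametric limb phantom
#'
#' A limb-like solid of revolution: a piecewise-linear radius-vs-height
#' profile revolved about the z axis, closed by a flat base disk at the
#' first height and a hemispherical distal cap (radius = last profile
#' radius) on top of the last height. The default profile emulates a
#' residuum-like shape: 75 mm maximum radius and 250 mm overall length,
#' in front of a green backdrop placed 600 mm from each camera so a
#' 500 mm depth threshold separates the two.
#'
#' Exact analytic ray intersections are available for every surface point,
#' which makes the phantom usable as ground truth for every downstream
#' stage.
#'
#' @param profile_heights increasing heights (mm) of the profile control
#'   points, starting at 0.
#' @param profile_radii radii (mm) at those heights, all positive.
#' @param color phantom surface color, 8-bit RGB.
#' @param backdrop_color backdrop color, 8-bit RGB (a green sheet).
#' @param backdrop_mm distance of the backdrop plane from each camera
#'   along its optical axis (mm).
#' @return An object of class `limb_phantom`.
#' @export
limb_phantom <- function(profile_heights = c(0, 50, 150, 210),
                         profile_radii = c(70, 75, 60, 40),
                         color = c(224, 172, 105),
                         backdrop_color = c(60, 179, 75),
                         backdrop_mm = 600) {
  check_that(length(profile_heights) == length(profile_radii) &&
             length(profile_heights) >= 2, "profile needs >= 2 control points")
  check_that(profile_heights[1] == 0, "profile must start at height 0")
  check_that(all(diff(profile_heights) > 0), "heights must be increasing")
  check_that(all(profile_radii > 0), "all radii must be positive")
  check_that(backdrop_mm > 0, "backdrop distance must be positive")
  n <- length(profile_heights)
  structure(list(profile_heights = as.numeric(profile_heights),
                 profile_radii = as.numeric(profile_radii),
                 cap_center_z = profile_heights[n],
                 cap_radius = profile_radii[n],
                 tip_z = profile_heights[n] + profile_radii[n],
                 color = as.numeric(color),
                 backdrop_color = as.numeric(backdrop_color),
                 backdrop_mm = backdrop_mm),
            class = "limb_phantom")
}

#' Phantom radius at a height
#'
#' The analytic profile: linear interpolation between control points along
#' the shaft, the sphere equation on the cap, `NA` outside `[0, tip]`.
#'
#' @param phantom A [limb_phantom()].
#' @param z heights (mm).
#' @return Radii (mm).
#' @export
phantom_radius <- function(phantom, z) {
  stopifnot(inherits(phantom, "limb_phantom"))
  r <- rep(NA_real_, length(z))
  shaft <- z >= 0 & z <= phantom$cap_center_z
  r[shaft] <- stats::approx(phantom$profile_heights, phantom$profile_radii,
                            xout = z[shaft])$y
  cap <- z > phantom$cap_center_z & z <= phantom$tip_z
  r[cap] <- sqrt(pmax(0, phantom$cap_radius^2 - (z[cap] - phantom$cap_center_z)^2))
  r
}

# First positive intersection parameter of rays (origins + t * dirs) with
# the phantom surface; Inf where a ray misses. Fully vectorised: each
# profile segment is a cone frustum (one quadratic per ray), plus the cap
# sphere and the base disk.
ray_cast_phantom <- function(phantom, origins, dirs, t_min = 1e-9) {
  o <- as_point_matrix(origins, "origins")
  d <- as_point_matrix(dirs, "dirs")
  if (nrow(o) == 1 && nrow(d) > 1) o <- o[rep(1, nrow(d)), , drop = FALSE]
  n <- nrow(d)
  best <- rep(Inf, n)

  consider <- function(t, valid) {
    ok <- valid & is.finite(t) & t > t_min & t < best
    best[ok] <<- t[ok]
  }

  hs <- phantom$profile_heights
  rs <- phantom$profile_radii
  for (k in seq_len(length(hs) - 1)) {
    z0 <- hs[k]; z1 <- hs[k + 1]
    r0 <- rs[k]; m <- (rs[k + 1] - rs[k]) / (z1 - z0)
    rb <- r0 + m * (o[, 3] - z0)          # profile radius at each ray origin's z
    A <- d[, 1]^2 + d[, 2]^2 - m^2 * d[, 3]^2
    B <- 2 * (o[, 1] * d[, 1] + o[, 2] * d[, 2] - m * d[, 3] * rb)
    C <- o[, 1]^2 + o[, 2]^2 - rb^2
    disc <- B^2 - 4 * A * C
    quad <- abs(A) > 1e-12
    sq <- sqrt(pmax(disc, 0))
    for (sgn in c(-1, 1)) {
      t <- ifelse(quad, (-B + sgn * sq) / (2 * A), -C / B)
      z <- o[, 3] + t * d[, 3]
      valid <- ifelse(quad, disc >= 0, abs(B) > 1e-12) &
        z >= z0 & z <= z1 & (rb + m * (z - o[, 3])) >= 0
      consider(t, valid)
      if (!any(quad)) break
    }
  }

  # hemispherical cap
  oz <- o[, 3] - phantom$cap_center_z
  B <- 2 * (o[, 1] * d[, 1] + o[, 2] * d[, 2] + oz * d[, 3])
  C <- o[, 1]^2 + o[, 2]^2 + oz^2 - phantom$cap_radius^2
  A <- rowSums(d^2)
  disc <- B^2 - 4 * A * C
  sq <- sqrt(pmax(disc, 0))
  for (sgn in c(-1, 1)) {
    t <- (-B + sgn * sq) / (2 * A)
    z <- o[, 3] + t * d[, 3]
    consider(t, disc >= 0 & z >= phantom$cap_center_z)
  }

  # base disk at z = 0
  dz <- d[, 3]
  t <- -o[, 3] / dz
  x <- o[, 1] + t * d[, 1]
  y <- o[, 2] + t * d[, 2]
  consider(t, abs(dz) > 1e-12 & (x^2 + y^2) <= rs[1]^2)

  best
}

#' Analytic outward surface normal at phantom surface points
#'
#' Classifies each point as base disk, revolved wall or cap and returns
#' the exact outward unit normal there: `(0, 0, -1)` on the base,
#' `(cos t, sin t, -r'(z)) / sqrt(1 + r'(z)^2)` on the wall, and the
#' radial sphere direction on the cap.
#'
#' @param phantom A [limb_phantom()].
#' @param points N x 3 matrix of points on (or near) the surface.
#' @return N x 3 matrix of unit normals.
#' @export
phantom_surface_normal <- function(phantom, points) {
  stopifnot(inherits(phantom, "limb_phantom"))
  p <- as_point_matrix(points)
  n <- matrix(0, nrow(p), 3)
  rho <- sqrt(p[, 1]^2 + p[, 2]^2)
  base <- p[, 3] <= 1e-9 & rho < phantom$profile_radii[1] - 1e-9
  cap <- p[, 3] > phantom$cap_center_z
  wall <- !base & !cap
  n[base, 3] <- -1
  if (any(cap)) {
    d <- p[cap, , drop = FALSE]
    d[, 3] <- d[, 3] - phantom$cap_center_z
    n[cap, ] <- d / sqrt(rowSums(d^2))
  }
  if (any(wall)) {
    hs <- phantom$profile_heights
    rs <- phantom$profile_radii
    seg <- pmin(pmax(findInterval(p[wall, 3], hs, rightmost.closed = TRUE), 1),
                length(hs) - 1)
    m <- (rs[seg + 1] - rs[seg]) / (hs[seg + 1] - hs[seg])
    ct <- p[wall, 1] / pmax(rho[wall], 1e-12)
    st <- p[wall, 2] / pmax(rho[wall], 1e-12)
    nw <- cbind(ct, st, -m) / sqrt(1 + m^2)
    n[wall, ] <- nw
  }
  n
}

#' Dense analytic surface sample of a phantom
#'
#' Points covering the whole closed surface — wall, cap and base disk —
#' at roughly `step_mm` spacing, each with its exact outward normal. The
#' oracle input for surface-reconstruction tests.
#'
#' @param phantom A [limb_phantom()].
#' @param step_mm target sample spacing (mm).
#' @return A [point_cloud()] with normals.
#' @export
phantom_surface_sample <- function(phantom, step_mm = 2) {
  stopifnot(inherits(phantom, "limb_phantom"))
  check_that(step_mm > 0, "step must be positive")
  gt <- ground_truth_mesh(phantom, n_theta = max(8, ceiling(
    2 * pi * max(phantom$profile_radii) / step_mm)), edge_mm = step_mm)
  pts <- gt$vertices
  # fill the base disk with concentric rings
  r0 <- phantom$profile_radii[1]
  radii <- seq(step_mm, r0 - step_mm / 2, by = step_mm)
  disk <- do.call(rbind, lapply(radii, function(r) {
    k <- max(4, ceiling(2 * pi * r / step_mm))
    th <- 2 * pi * (seq_len(k) - 1) / k
    cbind(r * cos(th), r * sin(th), 0)
  }))
  pts <- rbind(pts, disk)
  point_cloud(pts, normals = phantom_surface_normal(phantom, pts))
}

#' Analytic ground-truth mesh of a phantom
#'
#' Revolves the profile into a watertight triangle mesh: rings of
#' `n_theta` vertices along the shaft and the cap, a base-centre fan and
#' a tip fan, all outward-oriented.
#'
#' @param phantom A [limb_phantom()].
#' @param n_theta angular resolution (vertices per ring).
#' @param edge_mm target edge length along the profile (mm).
#' @return A watertight [triangle_mesh()].
#' @export
ground_truth_mesh <- function(phantom, n_theta = 128, edge_mm = 3) {
  stopifnot(inherits(phantom, "limb_phantom"))
  check_that(n_theta >= 8 && edge_mm > 0, "resolution parameters out of range")
  hs <- phantom$profile_heights
  ring_z <- unlist(lapply(seq_len(length(hs) - 1), function(k) {
    nseg <- max(1, ceiling((hs[k + 1] - hs[k]) / edge_mm))
    seq(hs[k], hs[k + 1], length.out = nseg + 1)[-(nseg + 1)]
  }))
  ring_z <- c(ring_z, hs[length(hs)])
  ring_r <- phantom_radius(phantom, ring_z)
  # cap rings (polar angle), excluding the junction ring already present
  R <- phantom$cap_radius
  n_phi <- max(2, ceiling((pi / 2 * R) / edge_mm))
  phi <- seq(0, pi / 2, length.out = n_phi + 1)[-c(1, n_phi + 1)]
  ring_z <- c(ring_z, phantom$cap_center_z + R * sin(phi))
  ring_r <- c(ring_r, R * cos(phi))

  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  n_ring <- length(ring_z)
  V <- do.call(rbind, lapply(seq_len(n_ring), function(i)
    cbind(ring_r[i] * cos(theta), ring_r[i] * sin(theta), ring_z[i])))
  base_c <- nrow(V) + 1L
  tip <- nrow(V) + 2L
  V <- rbind(V, c(0, 0, 0), c(0, 0, phantom$tip_z))

  jn <- seq_len(n_theta)
  jp <- c(2:n_theta, 1L)
  F <- matrix(0L, 0, 3)
  # base fan, outward normal -z
  F <- rbind(F, cbind(base_c, jp, jn))
  # side strips
  for (i in seq_len(n_ring - 1)) {
    a <- (i - 1) * n_theta
    b <- i * n_theta
    F <- rbind(F,
               cbind(a + jn, a + jp, b + jp),
               cbind(a + jn, b + jp, b + jn))
  }
  # tip fan
  a <- (n_ring - 1) * n_theta
  F <- rbind(F, cbind(a + jn, a + jp, tip))
  triangle_mesh(V, F)
}
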