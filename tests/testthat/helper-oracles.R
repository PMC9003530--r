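# Independent brute-force oracles, deliberately naive: they re-derive each
# operation from its definition so the vectorised implementations can be
# checked against them on small random instances.

naive_median_pass <- function(mask, size) {
  r <- (size - 1) / 2
  h <- nrow(mask); w <- ncol(mask)
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 2 - i, i)
    ifelse(i > n, 2 * n - i, i)
  }
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      win <- mask[reflect(i + (-r:r), h), reflect(j + (-r:r), w)]
      out[i, j] <- sort(as.vector(win))[(size^2 + 1) / 2]
    }
  }
  out
}

naive_erode_pass <- function(mask, size) {
  r <- (size - 1) / 2
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ii <- i + (-r:r); jj <- j + (-r:r)
      inside <- ii >= 1 & ii <= h
      jnside <- jj >= 1 & jj <= w
      if (all(inside) && all(jnside)) out[i, j] <- all(mask[ii, jj])
      else out[i, j] <- FALSE  # out-of-bounds counts false
    }
  }
  out
}

# Exhaustive search over all 256 candidate thresholds of the weighted
# within-class variance; same flat-run midpoint tie-break.
naive_otsu <- function(gray) {
  g <- as.integer(round(as.vector(gray)))
  within <- rep(Inf, 255)
  for (th in 0:254) {
    c0 <- g[g <= th]
    c1 <- g[g > th]
    if (length(c0) == 0 || length(c1) == 0) next
    v0 <- if (length(c0) > 1) mean((c0 - mean(c0))^2) else 0
    v1 <- if (length(c1) > 1) mean((c1 - mean(c1))^2) else 0
    within[th + 1] <- length(c0) / length(g) * v0 + length(c1) / length(g) * v1
  }
  best <- which(within == min(within))
  as.integer(floor((min(best) + max(best)) / 2)) - 1L
}

naive_hausdorff <- function(A, B) {
  d <- sqrt(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B))
  max(max(apply(d, 1, min)), max(apply(d, 2, min)))
}

naive_voxel_count <- function(points, voxel) {
  keys <- apply(floor(points / voxel), 1, paste, collapse = "/")
  length(unique(keys))
}

random_rotation <- function() {
  axis <- rnorm(3)
  rotation_about(axis, runif(1, 0, pi))
}

# Small scaled-down capture geometry shared by the cheaper pipeline tests:
# same rig proportions, 8x fewer pixels per axis.
small_intrinsics <- function() {
  fx <- 160 / tan(34.7 * pi / 180)
  camera_intrinsics(320, 180, fx, fx, 160, 90)
}

small_layout <- function() rig_layout(intrinsics = small_intrinsics())

mesh_edge_keys_test <- function(mesh) limbscan:::mesh_edge_keys(mesh)
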