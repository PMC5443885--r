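# Low-level array primitives shared by the phantom generator and the BSI code.
# Everything works on plain 3D numeric/logical arrays; no geometry metadata.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the session RNG with `seed`, evaluates `expr`, and restores whatever
#' RNG state was in place before, so seeded generators never perturb the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation so the state can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Shift a 3D array by `s` voxels along `axis`, filling vacated planes with
# `fill` (zero-fill semantics: outside the grid is background).
shift_fill <- function(a, s, axis, fill = 0) {
  if (s == 0) return(a)
  d <- dim(a)
  out <- array(fill, dim = d)
  n <- d[axis]
  if (abs(s) >= n) return(out)
  src <- if (s > 0) seq_len(n - s) else seq(1 - s, n)
  dst <- if (s > 0) seq(1 + s, n) else seq_len(n + s)
  idx_src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx_dst <- idx_src
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# Circular shift along one axis (used by the motion model, which convolves
# periodically so the image sum is conserved exactly).
shift_circ <- function(a, s, axis) {
  d <- dim(a)
  n <- d[axis]
  s <- ((s %% n) + n) %% n
  if (s == 0) return(a)
  ord <- c(seq(n - s + 1, n), seq_len(n - s))
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[axis]] <- ord
  a[idx[[1]], idx[[2]], idx[[3]]]
}

# One round of binary dilation / erosion with the 6-connected (face) cross.
# Outside the grid counts as background for both operations.
dilate_once <- function(m) {
  out <- m
  for (axis in 1:3) {
    out <- out | shift_fill(m, 1L, axis, fill = FALSE) |
      shift_fill(m, -1L, axis, fill = FALSE)
  }
  out
}

erode_once <- function(m) {
  out <- m
  for (axis in 1:3) {
    out <- out & shift_fill(m, 1L, axis, fill = FALSE) &
      shift_fill(m, -1L, axis, fill = FALSE)
  }
  out
}

dilate_n <- function(m, n) {
  stopifnot(n >= 0)
  for (i in seq_len(n)) m <- dilate_once(m)
  m
}

erode_n <- function(m, n) {
  stopifnot(n >= 0)
  for (i in seq_len(n)) m <- erode_once(m)
  m
}

# Separable convolution of a 3D array with a 1-D kernel along one axis,
# zero-filled at the borders.
conv_axis_fill <- function(a, kernel, axis) {
  half <- (length(kernel) - 1L) / 2L
  out <- array(0, dim = dim(a))
  for (i in seq_along(kernel)) {
    s <- i - 1L - half
    out <- out + kernel[i] * shift_fill(a, s, axis, fill = 0)
  }
  out
}

gaussian_kernel_1d <- function(sigma_vox) {
  half <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-half, half)
  k <- exp(-0.5 * (x / sigma_vox)^2)
  k / sum(k)
}

# Mask-weighted separable Gaussian smoothing: values outside `mask` do not
# leak in, and the result is renormalised by the smoothed mask so the filter
# behaves like a local weighted mean near the mask edge.
smooth_gaussian_masked <- function(a, mask, fwhm_mm, voxel_size) {
  w <- array(as.numeric(mask), dim = dim(a))
  v <- a * w
  for (axis in 1:3) {
    sigma_vox <- (fwhm_mm / 2.3548) / voxel_size[axis]
    if (sigma_vox <= 0) next
    k <- gaussian_kernel_1d(sigma_vox)
    v <- conv_axis_fill(v, k, axis)
    w <- conv_axis_fill(w, k, axis)
  }
  out <- array(0, dim = dim(a))
  nz <- w > 1e-12
  out[nz] <- v[nz] / w[nz]
  out
}

# Millimetre coordinates of voxel centres relative to an offset grid centre.
# The sub-voxel offset makes voxel distances generically distinct, so masks
# thresholded on sorted distances hit requested voxel counts exactly.
voxel_coords_mm <- function(grid_shape, voxel_size,
                            centre_offset = c(0.1234, 0.2153, 0.0817)) {
  ctr <- (grid_shape + 1) / 2 * voxel_size + centre_offset
  list(
    x = (seq_len(grid_shape[1]) * voxel_size[1]) - ctr[1],
    y = (seq_len(grid_shape[2]) * voxel_size[2]) - ctr[2],
    z = (seq_len(grid_shape[3]) * voxel_size[3]) - ctr[3]
  )
}

# Squared distance field (mm^2) from the offset grid centre, optionally with
# per-axis scaling (for ellipsoids pass semiaxes; for spheres pass c(1,1,1)
# and compare against radius^2).
quad_field <- function(coords, centre = c(0, 0, 0), scale = c(1, 1, 1)) {
  nx <- length(coords$x); ny <- length(coords$y); nz <- length(coords$z)
  qx <- ((coords$x - centre[1]) / scale[1])^2
  qy <- ((coords$y - centre[2]) / scale[2])^2
  qz <- ((coords$z - centre[3]) / scale[3])^2
  array(rep(qx, times = ny * nz), dim = c(nx, ny, nz)) +
    array(rep(rep(qy, each = nx), times = nz), dim = c(nx, ny, nz)) +
    array(rep(qz, each = nx * ny), dim = c(nx, ny, nz))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
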