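#' Digital phantom for acquisition simulation
#'
#' A 3D nonnegative intensity array standing in for the imaged head, with a
#' guard margin of empty field of view around the support so that rigid
#' displacements up to the coached motion bounds do not push signal outside
#' the FOV.
#'
#' @param shape Length-3 integer vector of array dimensions, each >= 16.
#' @param kind `"gaussian_blob"` (isotropic Gaussian, analytically
#'   convenient), `"shepp_logan_3d"` (the standard ten-ellipsoid head
#'   phantom), or `"multi_ellipsoid"` (randomly placed ellipsoids with
#'   distinct intensity levels so motion produces visible ghosting).
#' @param voxel_size Voxel edge length(s) in mm (scalar or length 3;
#'   default 3).
#' @param partition_axis Axis used as the partition (slow phase-encode)
#'   direction (default 3).
#' @param seed Seed for the random `multi_ellipsoid` layout.
#' @return An object of class `phantom`: list with `data`, `voxel_size`,
#'   `partition_axis` and `rotation_center` (mm, defaults to the intensity
#'   centroid).
#' @export
make_phantom <- function(shape = c(32, 32, 32),
                         kind = c("gaussian_blob", "shepp_logan_3d",
                                  "multi_ellipsoid"),
                         voxel_size = 3, seed = 1) {
  kind <- match.arg(kind)
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 16))
    stop("shape must have 3 axes of at least 16 voxels")
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  data <- switch(kind,
    gaussian_blob = gaussian_blob(shape),
    shepp_logan_3d = shepp_logan_3d(shape),
    multi_ellipsoid = multi_ellipsoid(shape, seed))
  ctr <- centroid_mm(data, voxel_size)
  structure(list(data = data, voxel_size = voxel_size,
                 partition_axis = 3L, rotation_center = ctr, kind = kind),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> ", x$kind, " ", paste(dim(x$data), collapse = "x"),
      " @ ", paste(signif(x$voxel_size, 3), collapse = "x"), " mm\n",
      sep = "")
  invisible(x)
}

centroid_mm <- function(data, voxel_size) {
  d <- dim(data)
  tot <- sum(data)
  if (tot == 0) return((d - 1) / 2 * voxel_size)
  sums <- lapply(1:3, function(ax) apply(data, ax, sum))
  vapply(1:3, function(ax)
    sum((seq_len(d[ax]) - 1) * sums[[ax]]) / tot * voxel_size[ax],
    numeric(1))
}

voxel_grids <- function(shape) {
  list(x = seq_len(shape[1]) - 1,
       y = seq_len(shape[2]) - 1,
       z = seq_len(shape[3]) - 1)
}

gaussian_blob <- function(shape) {
  c0 <- (shape - 1) / 2
  sig <- shape / 7  # support well inside the FOV, ~3.5 sigma guard
  g <- voxel_grids(shape)
  gx <- exp(-(g$x - c0[1])^2 / (2 * sig[1]^2))
  gy <- exp(-(g$y - c0[2])^2 / (2 * sig[2]^2))
  gz <- exp(-(g$z - c0[3])^2 / (2 * sig[3]^2))
  arr <- outer(outer(gx, gy), gz)
  arr[arr < 1e-6] <- 0
  100 * arr
}

# ellipsoids: rows of (intensity, semiaxes a,b,c, center cx,cy,cz) in
# fractions of the half-FOV, center offsets in fractions of the FOV.
add_ellipsoid <- function(arr, shape, val, ax, cen, angle_deg = 0) {
  c0 <- (shape - 1) / 2
  g <- voxel_grids(shape)
  xs <- (g$x - c0[1] - cen[1] * c0[1]) / (ax[1] * c0[1])
  ys <- (g$y - c0[2] - cen[2] * c0[2]) / (ax[2] * c0[2])
  zs <- (g$z - c0[3] - cen[3] * c0[3]) / (ax[3] * c0[3])
  if (angle_deg != 0) {
    th <- angle_deg * pi / 180
    X <- outer(xs, rep(1, shape[2]))
    Y <- outer(rep(1, shape[1]), ys)
    Xr <- X * cos(th) + Y * sin(th)
    Yr <- -X * sin(th) + Y * cos(th)
    r2xy <- Xr^2 + Yr^2
  } else {
    r2xy <- outer(xs^2, rep(1, shape[2])) + outer(rep(1, shape[1]), ys^2)
  }
  for (k in seq_len(shape[3])) {
    inside <- r2xy + zs[k]^2 <= 1
    arr[, , k][inside] <- arr[, , k][inside] + val
  }
  arr
}

# 3D Shepp-Logan (Kak & Slaney ellipsoid parameters, z-rotations only),
# rescaled so the outer skull ellipsoid keeps a ~25% FOV guard margin.
shepp_logan_3d <- function(shape) {
  e <- matrix(c(
    #  val    a     b     c     x0     y0     z0   phi
      1.00, 0.69, 0.92, 0.81,  0.00,  0.00,  0.00,   0,
     -0.80, 0.66, 0.87, 0.78,  0.00, -0.02,  0.00,   0,
     -0.20, 0.11, 0.31, 0.22,  0.22,  0.00,  0.00, -18,
     -0.20, 0.16, 0.41, 0.28, -0.22,  0.00,  0.00,  18,
      0.10, 0.21, 0.25, 0.41,  0.00,  0.35, -0.15,   0,
      0.10, 0.046, 0.046, 0.05, 0.00,  0.10,  0.25,  0,
      0.10, 0.046, 0.046, 0.05, 0.00, -0.10,  0.25,  0,
      0.10, 0.046, 0.023, 0.05, -0.08, -0.605, 0.00,  0,
      0.10, 0.023, 0.023, 0.02,  0.00, -0.606, 0.00,  0,
      0.10, 0.023, 0.046, 0.02,  0.06, -0.605, 0.00,  0
  ), ncol = 8, byrow = TRUE)
  scale <- 0.75
  arr <- array(0, shape)
  for (i in seq_len(nrow(e)))
    arr <- add_ellipsoid(arr, shape, e[i, 1], e[i, 2:4] * scale,
                         e[i, 5:7] * scale, e[i, 8])
  arr[arr < 0] <- 0
  100 * arr
}

multi_ellipsoid <- function(shape, seed) {
  set.seed(seed)
  arr <- array(0, shape)
  arr <- add_ellipsoid(arr, shape, 60, c(0.62, 0.68, 0.60), c(0, 0, 0))
  n_inner <- 4
  for (i in seq_len(n_inner)) {
    ax <- stats::runif(3, 0.08, 0.22)
    cen <- stats::runif(3, -0.3, 0.3)
    val <- sample(c(-35, -20, 25, 45, 70), 1)
    arr <- add_ellipsoid(arr, shape, val, ax, cen,
                         stats::runif(1, -45, 45))
  }
  arr[arr < 0] <- 0
  arr
}
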