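# Rigid-body 6-DOF pose handling and trilinear resampling.
#
# A pose is c(x, y, z, pitch, roll, yaw): translations in mm, rotations in
# degrees. Rotations are extrinsic and applied pitch (about x), then roll
# (about y), then yaw (about z), i.e. R = Rz %*% Ry %*% Rx, about a stated
# rotation centre: x' = R (x - c) + c + t.

rot_mat <- function(pitch, roll, yaw) {
  p <- pitch * pi / 180; r <- roll * pi / 180; y <- yaw * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(p), sin(p), 0, -sin(p), cos(p)), 3, 3)
  Ry <- matrix(c(cos(r), 0, -sin(r), 0, 1, 0, sin(r), 0, cos(r)), 3, 3)
  Rz <- matrix(c(cos(y), sin(y), 0, -sin(y), cos(y), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Homogeneous matrix of a 6-DOF pose
#'
#' @param pose Numeric length-6: `c(x, y, z, pitch, roll, yaw)` in mm and
#'   degrees.
#' @param center Rotation centre in mm (length 3).
#' @return A 4x4 homogeneous transform acting on mm coordinates.
#' @export
pose_matrix <- function(pose, center = c(0, 0, 0)) {
  R <- rot_mat(pose[4], pose[5], pose[6])
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- center + pose[1:3] - R %*% center
  A
}

is_identity_pose <- function(pose, tol = 0) all(abs(pose) <= tol)

# Trilinear interpolation of vol at 0-based voxel coordinates (3 x N
# matrix). Points outside the array sample zero. Coordinates within 1e-9 of
# a grid plane are snapped so that integer-voxel shifts are exact.
trilinear_sample <- function(vol, pts) {
  d <- dim(vol)
  i0 <- floor(pts)
  f <- pts - i0
  snap_hi <- f > 1 - 1e-9
  i0[snap_hi] <- i0[snap_hi] + 1
  f[snap_hi] <- 0
  f[f < 1e-9] <- 0
  fx <- f[1, ]; fy <- f[2, ]; fz <- f[3, ]
  ix <- i0[1, ] + 1; iy <- i0[2, ] + 1; iz <- i0[3, ] + 1
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  gather <- function(ii, jj, kk, w) {
    out <- numeric(length(ii))
    use <- w > 0 & ii >= 1 & ii <= nx & jj >= 1 & jj <= ny &
      kk >= 1 & kk <= nz
    if (any(use))
      out[use] <- vol[(kk[use] - 1) * nx * ny + (jj[use] - 1) * nx +
                        ii[use]] * w[use]
    out
  }
  gx <- 1 - fx; gy <- 1 - fy; gz <- 1 - fz
  gather(ix,     iy,     iz,     gx * gy * gz) +
  gather(ix + 1, iy,     iz,     fx * gy * gz) +
  gather(ix,     iy + 1, iz,     gx * fy * gz) +
  gather(ix + 1, iy + 1, iz,     fx * fy * gz) +
  gather(ix,     iy,     iz + 1, gx * gy * fz) +
  gather(ix + 1, iy,     iz + 1, fx * gy * fz) +
  gather(ix,     iy + 1, iz + 1, gx * fy * fz) +
  gather(ix + 1, iy + 1, iz + 1, fx * fy * fz)
}

# Fast trilinear variant for registration cost evaluation: coordinates are
# clamped to the array instead of bounds-checked per corner. Valid when the
# sampled object is surrounded by a zero guard band, as the phantoms are.
trilinear_clamped <- function(vol, pts, d) {
  px <- pmin(pmax(pts[1, ], 0), d[1] - 1.000001)
  py <- pmin(pmax(pts[2, ], 0), d[2] - 1.000001)
  pz <- pmin(pmax(pts[3, ], 0), d[3] - 1.000001)
  ix <- floor(px); iy <- floor(py); iz <- floor(pz)
  fx <- px - ix; fy <- py - iy; fz <- pz - iz
  nx <- d[1]; nxy <- d[1] * d[2]
  base <- iz * nxy + iy * nx + ix + 1
  gx <- 1 - fx; gy <- 1 - fy; gz <- 1 - fz
  vol[base] * (gx * gy * gz) +
    vol[base + 1] * (fx * gy * gz) +
    vol[base + nx] * (gx * fy * gz) +
    vol[base + nx + 1] * (fx * fy * gz) +
    vol[base + nxy] * (gx * gy * fz) +
    vol[base + nxy + 1] * (fx * gy * fz) +
    vol[base + nxy + nx] * (gx * fy * fz) +
    vol[base + nxy + nx + 1] * (fx * fy * fz)
}

# mm coordinates of every voxel, as a 3 x N matrix (column-major order)
grid_coords_mm <- function(shape, voxel_size) {
  xs <- (seq_len(shape[1]) - 1) * voxel_size[1]
  ys <- (seq_len(shape[2]) - 1) * voxel_size[2]
  zs <- (seq_len(shape[3]) - 1) * voxel_size[3]
  rbind(rep(xs, times = shape[2] * shape[3]),
        rep(rep(ys, each = shape[1]), times = shape[3]),
        rep(zs, each = shape[1] * shape[2]))
}

#' Apply a rigid-body pose to an image volume
#'
#' Rotates the volume about `center` (extrinsic pitch-x, roll-y, yaw-z
#' order) and then translates it, resampling on the original grid. The
#' identity pose returns the input unchanged bitwise; integer-voxel pure
#' translations are exact array shifts under trilinear interpolation.
#' Voxels sampled from outside the field of view are set to zero, and if
#' the transformed support reaches the FOV boundary the result carries the
#' attribute `clipped = TRUE`.
#'
#' @param volume 3D numeric array, or a `phantom` (whose voxel size and
#'   rotation centre are then used as defaults).
#' @param pose Length-6 pose `c(x, y, z, pitch, roll, yaw)` (mm, deg).
#' @param center Rotation centre in mm; defaults to the volume centre (or
#'   the phantom's stored centre).
#' @param voxel_size Voxel size in mm (scalar or length 3, default 1).
#' @param interp Interpolation scheme; `"trilinear"` (only scheme in v1).
#' @return The transformed 3D array.
#' @export
apply_rigid <- function(volume, pose, center = NULL, voxel_size = 1,
                        interp = "trilinear") {
  if (inherits(volume, "phantom")) {
    if (is.null(center)) center <- volume$rotation_center
    voxel_size <- volume$voxel_size
    volume <- volume$data
  }
  interp <- match.arg(interp, "trilinear")
  d <- dim(volume)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  if (is.null(center)) center <- (d - 1) / 2 * voxel_size
  if (is_identity_pose(pose)) return(volume)
  A <- pose_matrix(pose, center)
  out <- resample_affine(volume, A, voxel_size)
  attr(out, "clipped") <- support_clipped(volume, A, voxel_size)
  out
}

# resample volume under forward transform A (mm coords): output(x) =
# volume(A^-1 x)
resample_affine <- function(volume, A, voxel_size) {
  d <- dim(volume)
  Ainv <- solve(A)
  pts <- grid_coords_mm(d, voxel_size)
  src <- Ainv[1:3, 1:3] %*% pts + Ainv[1:3, 4]
  src <- src / voxel_size
  array(trilinear_sample(volume, src), d)
}

support_clipped <- function(volume, A, voxel_size) {
  d <- dim(volume)
  thr <- 1e-6 * max(abs(volume))
  idx <- which(volume > thr, arr.ind = TRUE)
  if (nrow(idx) == 0) return(FALSE)
  lo <- (apply(idx, 2, min) - 1) * voxel_size
  hi <- (apply(idx, 2, max) - 1) * voxel_size
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  moved <- A[1:3, 1:3] %*% t(corners) + A[1:3, 4]
  fov_hi <- (d - 1) * voxel_size
  any(moved < 0) || any(moved > fov_hi)
}
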