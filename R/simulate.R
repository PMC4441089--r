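#' Simulation configuration for 3D EPI acquisition
#'
#' @param pmc Logical: apply prospective motion correction? When on, the
#'   field of view is counter-transformed before every excitation using the
#'   pose reported by the (perfect) camera at time `t - pmc_latency`.
#' @param pmc_latency Correction latency in seconds (default 0: the update
#'   immediately before each excitation uses the current pose, so
#'   correction is exact up to interpolation). A latency of one TR emulates
#'   motion continuing between pose updates.
#' @param interp Interpolation for rotational resampling (`"trilinear"`).
#' @param noise_sd Image-domain Gaussian noise SD as a fraction of the
#'   mean intensity over the phantom support (default 0).
#' @param min_rotation Rotations whose angles are all below this threshold
#'   (degrees, default 0.02) are applied as their equivalent translation
#'   about the rotation centre instead of by image resampling: at tracker-
#'   noise angles the trilinear interpolation error would exceed the true
#'   rotation effect, and the phase-ramp path is exact.
#' @param seed Seed for the noise generator.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(pmc = FALSE, pmc_latency = 0, interp = "trilinear",
                       noise_sd = 0, min_rotation = 0.02, seed = NULL) {
  if (pmc_latency < 0) stop("pmc_latency must be >= 0")
  structure(list(pmc = isTRUE(pmc), pmc_latency = pmc_latency,
                 interp = match.arg(interp, "trilinear"),
                 noise_sd = noise_sd, min_rotation = min_rotation,
                 seed = seed),
            class = "sim_config")
}

trace_pose_at <- function(trace, t) {
  idx <- findInterval(t, trace$times)
  idx[idx < 1] <- 1
  cbind(trace$x[idx], trace$y[idx], trace$z[idx],
        trace$pitch[idx], trace$roll[idx], trace$yaw[idx])
}

check_trace_coverage <- function(trace, timing) {
  t_end <- timing$start_time + timing$n_volumes * timing$volume_duration
  if (max(trace$times) < t_end - timing$tr - 1e-9 ||
      min(trace$times) > timing$start_time + 1e-9)
    stop("trace does not cover the acquisition window [",
         timing$start_time, ", ", signif(t_end, 6), "] s")
  invisible(TRUE)
}

# Simulate the acquisition of one volume: for each excitation in
# partition_order, sample the head pose, optionally compose with the
# inverse of the camera-reported pose (PMC), rotate the phantom in image
# space, Fourier transform, keep the assigned k_z plane, and apply the
# residual translation as an exact phase ramp on that plane. `cache` keeps
# the FFT of the last rotated phantom across excitations and volumes.
sim_one_volume <- function(phantom, trace, timing, config, v, Ks, cache) {
  d <- dim(phantom$data)
  if (phantom$partition_axis != 3)
    stop("the simulator requires partition_axis = 3")
  P <- timing$partitions_per_volume
  if (d[3] != P)
    stop("phantom has ", d[3], " planes along the partition axis but ",
         "timing specifies ", P, " partitions per volume")
  ctr <- phantom$rotation_center
  vs <- phantom$voxel_size
  fx <- shifted_freqs(d[1]); fy <- shifted_freqs(d[2])
  fz <- shifted_freqs(d[3])
  vol_start <- timing$start_time + (v - 1) * timing$volume_duration
  t_exc <- vol_start + (seq_len(P) - 1) * timing$tr
  act <- trace_pose_at(trace, t_exc)
  rep_pose <- if (config$pmc) trace_pose_at(trace, t_exc - config$pmc_latency)

  K_out <- array(0i, d)
  for (m in seq_len(P)) {
    j <- timing$partition_order[m]
    A <- pose_matrix(act[m, ], ctr)
    if (config$pmc)
      A <- A %*% solve(pose_matrix(rep_pose[m, ], ctr))
    Rn <- A[1:3, 1:3]
    rot_tol <- max(1e-12, config$min_rotation * pi / 180)
    if (max(abs(Rn - diag(3))) < rot_tol) {
      K <- Ks
      dmm <- A[1:3, 4] - ctr + Rn %*% ctr
    } else {
      if (is.null(cache$R) || max(abs(cache$R - Rn)) > 1e-13) {
        Arot <- diag(4)
        Arot[1:3, 1:3] <- Rn
        Arot[1:3, 4] <- ctr - Rn %*% ctr
        rotated <- resample_affine(phantom$data, Arot, vs)
        cache$R <- Rn
        cache$K <- fftshift(stats::fft(rotated))
      }
      K <- cache$K
      dmm <- A[1:3, 4] - ctr + Rn %*% ctr
    }
    s <- dmm / vs  # residual translation in voxels
    ramp <- exp(-2i * pi * (outer(fx * s[1] / d[1], fy * s[2] / d[2], "+") +
                              fz[j] * s[3] / d[3]))
    K_out[, , j] <- K[, , j] * ramp
  }
  list(kspace = K_out,
       image = Mod(ifft(ifftshift(K_out))),
       poses = data.frame(volume = v, excitation = seq_len(P),
                          plane = timing$partition_order, time = t_exc,
                          x = act[, 1], y = act[, 2], z = act[, 3],
                          pitch = act[, 4], roll = act[, 5], yaw = act[, 6]))
}

#' Simulate the acquisition of a single 3D EPI volume
#'
#' One k_x-k_y partition plane is acquired per TR from the digital phantom
#' posed according to the motion trace at each excitation's start time
#' (nearest camera sample at or before it). Translations are applied as
#' exact phase ramps on the extracted k-plane; rotations by image-space
#' trilinear resampling before the Fourier transform. With PMC on and zero
#' latency the net pose is the identity and the reconstruction equals the
#' static one.
#'
#' @param phantom A [make_phantom()] object.
#' @param trace A [motion_trace()] covering the volume's acquisition
#'   window.
#' @param timing An [acq_timing()].
#' @param config A [sim_config()].
#' @param volume Index of the volume to simulate (default 1).
#' @return List with `kspace` (complex 3D array, DC-centred), `image`
#'   (magnitude reconstruction) and `poses` (per-excitation ground-truth
#'   head poses).
#' @export
simulate_volume <- function(phantom, trace, timing, config = sim_config(),
                            volume = 1) {
  check_trace_coverage_volume(trace, timing, volume)
  Ks <- fftshift(stats::fft(phantom$data))
  cache <- new.env(parent = emptyenv())
  out <- sim_one_volume(phantom, trace, timing, config, volume, Ks, cache)
  if (config$noise_sd > 0) {
    if (!is.null(config$seed)) set.seed(config$seed)
    out$image <- out$image +
      array(stats::rnorm(length(out$image),
                         sd = config$noise_sd * support_mean(phantom$data)),
            dim(out$image))
  }
  out
}

check_trace_coverage_volume <- function(trace, timing, v) {
  t0 <- timing$start_time + (v - 1) * timing$volume_duration
  t1 <- t0 + timing$volume_duration
  if (min(trace$times) > t0 + 1e-9 || max(trace$times) < t1 - timing$tr - 1e-9)
    stop("trace does not cover the acquisition window of volume ", v)
  invisible(TRUE)
}

#' Simulate a 4D 3D-EPI time series
#'
#' Concatenates [simulate_volume()] over all volumes of the timing object,
#' reusing the Fourier transform of the phantom across still periods, and
#' adds seeded image-domain Gaussian noise.
#'
#' @inheritParams simulate_volume
#' @return An object of class `recon_series`: list with `data` (4D array,
#'   x-y-z-volume), `voxel_size`, `timing`, `config` and `poses` (one row
#'   per RF excitation with the ground-truth head pose).
#' @export
simulate_series <- function(phantom, trace, timing, config = sim_config()) {
  check_trace_coverage(trace, timing)
  d <- dim(phantom$data)
  Ks <- fftshift(stats::fft(phantom$data))
  cache <- new.env(parent = emptyenv())
  data <- array(0, c(d, timing$n_volumes))
  poses <- vector("list", timing$n_volumes)
  if (!is.null(config$seed)) set.seed(config$seed)
  noise_sd <- config$noise_sd * support_mean(phantom$data)
  for (v in seq_len(timing$n_volumes)) {
    out <- sim_one_volume(phantom, trace, timing, config, v, Ks, cache)
    img <- out$image
    if (config$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), sd = noise_sd), d)
    data[, , , v] <- img
    poses[[v]] <- out$poses
  }
  structure(list(data = data, voxel_size = phantom$voxel_size,
                 timing = timing, config = config,
                 poses = do.call(rbind, poses)),
            class = "recon_series")
}

#' @export
print.recon_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<recon_series> ", d[4], " volumes of ",
      paste(d[1:3], collapse = "x"), " @ ",
      paste(signif(x$voxel_size, 3), collapse = "x"), " mm, PMC ",
      if (x$config$pmc) "on" else "off", "\n", sep = "")
  invisible(x)
}

#' Write / read a reconstructed series as NIfTI-1
#'
#' The 4D array is written with the voxel size and volume duration in the
#' header `pixdim`. Reading returns a plain list with `data`, `voxel_size`
#' and `tr_volume`; acquisition timing and ground-truth poses are not part
#' of the NIfTI format and travel separately (see [write_log()]).
#'
#' @param series A `recon_series` (or bare 4D/3D array).
#' @param path File path (`.nii` or `.nii.gz`).
#' @param voxel_size,tr_volume Used when `series` is a bare array.
#' @return `write_series` returns `path` invisibly; `read_series` the list
#'   above.
#' @export
write_series <- function(series, path, voxel_size = 1, tr_volume = 1) {
  if (inherits(series, "recon_series")) {
    voxel_size <- series$voxel_size
    tr_volume <- series$timing$volume_duration
    series <- series$data
  }
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  img <- RNifti::asNifti(series)
  RNifti::pixdim(img) <- c(voxel_size, tr_volume)[seq_len(length(dim(series)))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  list(data = array(as.numeric(img), dim(img)), voxel_size = pd[1:3],
       tr_volume = if (length(pd) >= 4) pd[4] else NA_real_)
}

# mean intensity over the object support (empty FOV excluded), the
# reference level for the image-noise fraction
support_mean <- function(data) mean(data[data > 0])
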