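series_data <- function(series) {
  if (inherits(series, "recon_series")) series$data
  else if (is.array(series) && length(dim(series)) == 4) series
  else stop("series must be a recon_series or a 4D array")
}

#' Discard initial volumes of a time series
#'
#' fMRI time series discard the first few volumes (five of 100 in the
#' protocol modelled here) to let the longitudinal magnetization reach
#' steady state; the same trimming is applied to per-volume motion metrics
#' so that indices stay aligned.
#'
#' @param series A `recon_series` or 4D array.
#' @param n Number of initial volumes to drop (default 5); must be smaller
#'   than the number of volumes.
#' @return The trimmed series (same class as the input). For a
#'   `recon_series` the timing, pose table and an attribute `discarded`
#'   are adjusted.
#' @export
discard_initial <- function(series, n = 5) {
  dat <- series_data(series)
  nv <- dim(dat)[4]
  if (n >= nv)
    stop("cannot discard ", n, " of ", nv, " volumes")
  if (n == 0) return(series)
  keep <- seq(n + 1, nv)
  if (inherits(series, "recon_series")) {
    series$data <- series$data[, , , keep, drop = FALSE]
    series$poses <- series$poses[series$poses$volume > n, , drop = FALSE]
    series$timing$n_volumes <- length(keep)
    series$timing$start_time <- series$timing$start_time +
      n * series$timing$volume_duration
    attr(series, "discarded") <- n
    series
  } else {
    dat[, , , keep, drop = FALSE]
  }
}

# small separable smoothing ([1 2 1]/4 per axis) applied to both images
# before the registration cost is evaluated; reduces the bias that
# single-sided trilinear interpolation smoothing otherwise introduces
smooth121 <- function(v) {
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    vp <- aperm(v, perm)
    d <- dim(vp)
    m <- matrix(vp, d[1])
    ms <- 0.5 * m + 0.25 * rbind(m[1, ], m[-d[1], , drop = FALSE]) +
      0.25 * rbind(m[-1, , drop = FALSE], m[d[1], ])
    v <- aperm(array(ms, d), order(perm))
  }
  v
}

#' Rigidly realign a time series to its first volume
#'
#' Estimates a 6-DOF pose for every volume by minimising the masked mean
#' squared intensity difference to the first volume, then reslices each
#' volume into the first volume's frame with trilinear interpolation. The
#' estimated pose is the movement of the volume relative to the first
#' (mm / degrees); reslicing applies its inverse.
#'
#' The cost is evaluated symmetrically: both images are resampled halfway
#' towards each other (the moving volume by half the candidate pose, the
#' reference by the inverse half), so that trilinear interpolation
#' smoothing affects both sides equally; a one-sided cost is biased
#' towards the identity, where resampling is error-free. Both images are
#' additionally lightly smoothed, as rigid-registration packages
#' conventionally do. Optimisation is a translation-only Nelder-Mead
#' stage followed by refinement of all six parameters, warm-started from
#' the previous volume's pose.
#'
#' @param series A `recon_series` or 4D array.
#' @param voxel_size Voxel size in mm when `series` is a bare array.
#' @param subsample Maximum number of in-mask voxels used in the cost
#'   function (default 2500); the mask is the first volume thresholded at
#'   15% of its maximum.
#' @param maxit Iteration cap for the final refinement stage (default
#'   600).
#' @return List with `series` (resliced, same class as input), `poses`
#'   (data frame of estimated 6-DOF poses per volume) and `converged`
#'   (logical per volume; non-converged volumes are passed through
#'   unregistered).
#' @export
realign <- function(series, voxel_size = NULL, subsample = 2500,
                    maxit = 600) {
  dat <- series_data(series)
  if (is.null(voxel_size))
    voxel_size <- if (inherits(series, "recon_series")) series$voxel_size
                  else rep(1, 3)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  d <- dim(dat)[1:3]
  nv <- dim(dat)[4]
  if (nv < 2) stop("realignment needs at least 2 volumes")
  ref <- smooth121(dat[, , , 1])
  sel <- which(ref > 0.15 * max(ref))
  if (length(sel) > subsample)
    sel <- sel[round(seq(1, length(sel), length.out = subsample))]
  pts_all <- grid_coords_mm(d, voxel_size)
  pts <- pts_all[, sel, drop = FALSE]
  ctr <- (d - 1) / 2 * voxel_size

  cost <- function(p, vol) {
    Ah <- pose_matrix(p / 2, ctr)
    Ahi <- pose_matrix(-p / 2, ctr)
    src_v <- (Ah[1:3, 1:3] %*% pts + Ah[1:3, 4]) / voxel_size
    src_r <- (Ahi[1:3, 1:3] %*% pts + Ahi[1:3, 4]) / voxel_size
    mean((trilinear_clamped(vol, src_v, d) -
            trilinear_clamped(ref, src_r, d))^2)
  }

  poses <- matrix(0, nv, 6,
                  dimnames = list(NULL, c("x", "y", "z",
                                          "pitch", "roll", "yaw")))
  converged <- rep(TRUE, nv)
  out <- dat
  p_prev <- rep(0, 6)
  for (v in seq(2, nv)) {
    vol <- smooth121(dat[, , , v])
    o1 <- stats::optim(p_prev[1:3], function(q) cost(c(q, p_prev[4:6]), vol),
                       method = "Nelder-Mead",
                       control = list(maxit = 300, reltol = 1e-9))
    o2 <- stats::optim(c(o1$par, p_prev[4:6]), cost, vol = vol,
                       method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-9))
    # Nelder-Mead routinely stops on the iteration cap close to the
    # optimum; restart the simplex from the current best a few times
    restarts <- 0
    while (o2$convergence != 0 && restarts < 3) {
      o2 <- stats::optim(o2$par, cost, vol = vol, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = 1e-9))
      restarts <- restarts + 1
    }
    if (o2$convergence != 0) {
      converged[v] <- FALSE
      p_prev <- rep(0, 6)
      next
    }
    p <- o2$par
    poses[v, ] <- p
    p_prev <- p
    if (!is_identity_pose(p, tol = 1e-8)) {
      # reslice the raw volume into the first volume's frame:
      # output(x) = vol(A_p x)
      out[, , , v] <- resample_affine(dat[, , , v],
                                      solve(pose_matrix(p, ctr)),
                                      voxel_size)
    }
  }
  if (inherits(series, "recon_series")) series$data <- out else series <- out
  list(series = series, poses = as.data.frame(poses), converged = converged)
}

#' Voxelwise temporal signal-to-noise ratio
#'
#' tSNR per voxel: the temporal mean divided by the temporal standard
#' deviation of the residuals after removing a first-order (linear) trend.
#' Voxels with zero residual variance get an `Inf` sentinel; summaries
#' ([mean_tsnr()]) exclude non-finite values.
#'
#' @param series A `recon_series` or 4D array with at least 3 volumes.
#' @return 3D array of tSNR values.
#' @export
compute_tsnr <- function(series) {
  dat <- series_data(series)
  d <- dim(dat)
  if (d[4] < 3) stop("tSNR needs at least 3 volumes")
  Y <- matrix(dat, prod(d[1:3]), d[4])
  tt <- seq_len(d[4]) - (d[4] + 1) / 2
  mu <- rowMeans(Y)
  beta <- (Y %*% tt) / sum(tt^2)
  resid <- Y - mu - beta %*% t(tt)
  s <- sqrt(rowSums(resid^2) / (d[4] - 2))
  tsnr <- ifelse(s == 0, Inf, mu / s)
  array(tsnr, d[1:3])
}

#' Mean tSNR inside a mask, excluding degenerate voxels
#' @param tsnr_map 3D array from [compute_tsnr()].
#' @param mask A [make_mask()] object or logical array.
#' @export
mean_tsnr <- function(tsnr_map, mask) {
  if (inherits(mask, "brain_mask")) mask <- mask$mask
  v <- tsnr_map[mask]
  mean(v[is.finite(v)])
}

#' Motion-gated reference image
#'
#' Averages all volumes whose partition-weighted integrated motion is at or
#' below the largest value observed during the baseline (instructed-still)
#' volumes, yielding a reference that is both low-motion and low-noise.
#' The baseline volumes always qualify by construction.
#'
#' @param series A `recon_series` or 4D array.
#' @param mpw Numeric vector of per-volume M_PW values aligned with the
#'   series' volumes, or a `volume_motion` data frame.
#' @param baseline Indices (into the series' volumes) of the baseline
#'   volumes.
#' @return List with `reference` (3D array), `indices` (contributing
#'   volumes) and `threshold` (mm-equivalent).
#' @export
build_reference <- function(series, mpw, baseline) {
  dat <- series_data(series)
  if (is.data.frame(mpw)) mpw <- mpw$M_PW
  nv <- dim(dat)[4]
  if (length(mpw) != nv)
    stop("mpw has length ", length(mpw), " but the series has ", nv,
         " volumes")
  if (length(baseline) == 0 || any(baseline < 1 | baseline > nv))
    stop("baseline must be a non-empty set of volume indices")
  thr <- max(mpw[baseline])
  idx <- which(mpw <= thr)
  d3 <- dim(dat)[1:3]
  ref <- array(rowMeans(matrix(dat[, , , idx, drop = FALSE],
                               prod(d3), length(idx))), d3)
  list(reference = ref, indices = idx, threshold = thr)
}

shift3d <- function(a, s) {
  d <- dim(a)
  out <- array(vector(typeof(a), 1), d)
  src <- lapply(1:3, function(ax) {
    i <- seq_len(d[ax]) - s[ax]
    i[i < 1 | i > d[ax]] <- NA
    i
  })
  ok <- lapply(src, function(i) !is.na(i))
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    a[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  out
}

neigh6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))

dilate6 <- function(b) {
  out <- b
  for (i in 1:6) out <- out | shift3d(b, neigh6[i, ])
  out
}

erode6 <- function(b) {
  out <- b
  for (i in 1:6) out <- out & shift3d(b, neigh6[i, ])
  out
}

largest_component <- function(b) {
  lab <- array(0, dim(b))
  lab[b] <- which(b)
  repeat {
    new <- lab
    for (i in 1:6) new <- pmax(new, shift3d(lab, neigh6[i, ]))
    new[!b] <- 0
    if (identical(new, lab)) break
    lab <- new
  }
  ids <- lab[b]
  keep <- as.numeric(names(which.max(table(ids))))
  lab == keep
}

#' Brain mask for quality metrics
#'
#' Builds the 3D mask over which tSNR and RMSE are summarised, excluding
#' background noise and surface voxels. Two provenances: a
#' threshold/morphology pipeline on the reference image (threshold at a
#' fraction of the robust maximum, 6-neighbourhood morphological closing,
#' largest connected component), or -- for simulated data where the truth
#' is known -- the phantom support eroded by one voxel.
#'
#' @param reference 3D array (reference image), or a `phantom` when
#'   `provenance = "phantom_support"`.
#' @param provenance `"threshold_morphology"` (default) or
#'   `"phantom_support"`.
#' @param threshold_frac Fraction of the robust (99th percentile) maximum
#'   used as intensity threshold (default 0.2).
#' @return An object of class `brain_mask`: list with `mask` (logical 3D
#'   array), `n_voxels` and `provenance`.
#' @export
make_mask <- function(reference,
                      provenance = c("threshold_morphology",
                                     "phantom_support"),
                      threshold_frac = 0.2) {
  provenance <- match.arg(provenance)
  if (inherits(reference, "phantom")) reference <- reference$data
  if (all(reference == 0)) stop("all-zero reference image")
  if (provenance == "phantom_support") {
    m <- erode6(reference > 1e-6 * max(reference))
  } else {
    pos <- reference[reference > 0]
    thr <- threshold_frac * stats::quantile(pos, 0.99, names = FALSE)
    m <- reference >= thr
    m <- erode6(dilate6(m))  # morphological closing
    m <- largest_component(m)
  }
  if (!any(m)) stop("empty mask")
  structure(list(mask = m, n_voxels = sum(m), provenance = provenance),
            class = "brain_mask")
}

#' Global mean-signal scaling and per-volume RMSE
#'
#' Scales the whole 4D data set by the mean signal of all in-mask voxels
#' (making the result invariant to global intensity scaling) and computes,
#' for each volume, the root-mean-square deviation from the reference
#' image over the mask. The reference is scaled by the same factor.
#'
#' @param series A `recon_series` or 4D array.
#' @param reference 3D reference array (e.g. from [build_reference()]).
#' @param mask A [make_mask()] object or logical 3D array.
#' @return List with `rmse` (data frame `volume_index`, `rmse` in scaled
#'   intensity units) and `scale` (the global scaling factor).
#' @export
scale_and_rmse <- function(series, reference, mask) {
  dat <- series_data(series)
  if (inherits(mask, "brain_mask")) mask <- mask$mask
  d <- dim(dat)
  if (!all(dim(mask) == d[1:3]) || !all(dim(reference) == d[1:3]))
    stop("series, reference and mask grids do not match")
  mvec <- which(mask)
  Y <- matrix(dat, prod(d[1:3]), d[4])[mvec, , drop = FALSE]
  sc <- mean(Y)
  if (sc == 0) stop("zero mean in-mask signal")
  Ys <- Y / sc
  refs <- reference[mvec] / sc
  rmse <- sqrt(colMeans((Ys - refs)^2))
  list(rmse = data.frame(volume_index = seq_len(d[4]), rmse = rmse),
       scale = sc)
}
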