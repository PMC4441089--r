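test_that("phantom construction is deterministic with the stated features", {
  p1 <- make_phantom(c(32, 32, 32), "gaussian_blob")
  # the grid centre lies between voxels 16 and 17 on each axis
  peak <- which(p1$data == max(p1$data), arr.ind = TRUE)
  expect_true(all(peak %in% 16:17))
  p2 <- make_phantom(c(32, 32, 32), "multi_ellipsoid", seed = 4)
  p3 <- make_phantom(c(32, 32, 32), "multi_ellipsoid", seed = 4)
  expect_identical(p2$data, p3$data)
  # internal contrast: at least 3 distinct quantized intensity levels
  lv <- unique(round(p2$data[p2$data > 0] / 5))
  expect_gte(length(lv), 3)
  sl <- make_phantom(c(24, 24, 24), "shepp_logan_3d")
  expect_true(all(sl$data >= 0) && max(sl$data) > 0)
  expect_error(make_phantom(c(8, 32, 32)), "at least 16")
})

test_that("rigid transforms honour identity, exact shifts and inversion", {
  vol <- phantom_me$data
  expect_identical(apply_rigid(vol, rep(0, 6), voxel_size = 3), vol)
  sh <- apply_rigid(vol, c(6, 0, -3, 0, 0, 0), voxel_size = 3)
  expect_equal(sh[3:32, , 1:31], vol[1:30, , 2:32])
  # small pose followed by its negation restores the volume closely
  # (smooth phantom: the residual is double-interpolation error)
  blob <- phantom_blob$data
  p <- c(2, -1.5, 1, 1.5, -1, 2)
  back <- apply_rigid(apply_rigid(blob, p, voxel_size = 3), -p,
                      voxel_size = 3)
  rel <- sqrt(mean((back - blob)^2)) / diff(range(blob))
  expect_lt(rel, 0.01)
})

test_that("static acquisition reproduces the phantom to FFT tolerance", {
  n <- round(timing_1vol$volume_duration * 80) + 10
  sv <- simulate_volume(phantom_blob, const_trace(n), timing_1vol,
                        sim_config())
  expect_lt(max(abs(sv$image - phantom_blob$data)) / max(phantom_blob$data),
            1e-8)
})

test_that("constant displacement matches the Fourier-shift oracle", {
  n <- round(timing_1vol$volume_duration * 80) + 10
  d <- c(4.5, -3, 6)  # non-integer voxel shifts at 3 mm voxels
  tr <- const_trace(n, c(d, 0, 0, 0))
  sv <- simulate_volume(phantom_blob, tr, timing_1vol, sim_config())
  # oracle: one whole-volume phase ramp, independent of the partition loop
  dd <- dim(phantom_blob$data)
  f <- function(nn) { k <- 0:(nn - 1); k[k >= nn / 2] <- k[k >= nn / 2] - nn; k }
  s <- d / 3
  ramp <- outer(outer(exp(-2i * pi * f(dd[1]) * s[1] / dd[1]),
                      exp(-2i * pi * f(dd[2]) * s[2] / dd[2])),
                exp(-2i * pi * f(dd[3]) * s[3] / dd[3]))
  oracle <- Mod(stats::fft(stats::fft(phantom_blob$data) * ramp,
                           inverse = TRUE) / prod(dd))
  expect_lt(max(abs(sv$image - oracle)) / max(oracle), 1e-8)
})

test_that("pure translations change k-space phase but not magnitude", {
  n <- round(timing_1vol$volume_duration * 80) + 10
  tr <- burst_trace(timing_1vol$volume_duration + 0.3, 0.5, 1.2,
                    amp = c(4, -3, 2, 0, 0, 0))
  sv <- simulate_volume(phantom_blob, tr, timing_1vol, sim_config())
  Ks <- simulate_volume(phantom_blob, const_trace(n), timing_1vol,
                        sim_config())$kspace
  expect_lt(max(abs(Mod(sv$kspace) - Mod(Ks))), 1e-8 * max(Mod(Ks)))
})

test_that("perfect zero-latency correction cancels any motion", {
  cfg <- motion_config("fast", duration = 10, baseline_still_volumes = 0,
                       seed = 7)
  tr <- generate_trace(cfg)
  sv <- simulate_volume(phantom_blob, tr, timing_1vol,
                        sim_config(pmc = TRUE, pmc_latency = 0))
  expect_lt(max(abs(sv$image - phantom_blob$data)) / max(phantom_blob$data),
            1e-8)
})

test_that("energy is conserved between assembled k-space and image", {
  tr <- burst_trace(timing_1vol$volume_duration + 0.3, 0.8, 0.5,
                    amp = c(3, 0, 0, 0, 2, 0))
  sv <- simulate_volume(phantom_blob, tr, timing_1vol, sim_config())
  K <- sv$kspace
  x <- stats::fft(K, inverse = TRUE) / length(K)
  expect_equal(sum(Mod(K)^2), length(K) * sum(Mod(x)^2),
               tolerance = 1e-6)
})

test_that("a central-partition burst damages the image more", {
  tm <- timing_1vol
  mkb <- function(t_on) burst_trace(tm$volume_duration + 0.3, t_on, 0.4,
                                    amp = c(5, 0, 0, 0, 0, 0))
  img_c <- simulate_volume(phantom_blob, mkb((17 - 1) * tm$tr), tm,
                           sim_config())$image
  img_p <- simulate_volume(phantom_blob, mkb(0.05), tm, sim_config())$image
  expect_gt(phantom_rmse(img_c, phantom_blob),
            phantom_rmse(img_p, phantom_blob))
})

test_that("series simulation spans the protocol duration and is seeded", {
  tm <- acq_timing(100, tr = 0.078, partitions_per_volume = 44)
  # 100 volumes x 44 excitations x 78 ms: 5 min 43 s of acquisition
  expect_equal(tm$n_volumes * tm$volume_duration, 343.2)

  tm8 <- acq_timing(8, partitions_per_volume = 32)
  cfg0 <- motion_config("none", duration = 8 * tm8$volume_duration + 1,
                        seed = 5)
  tr <- generate_trace(cfg0)
  s1 <- simulate_series(phantom_blob, tr, tm8,
                        sim_config(noise_sd = 0.02, seed = 3))
  s2 <- simulate_series(phantom_blob, tr, tm8,
                        sim_config(noise_sd = 0.02, seed = 3))
  expect_identical(s1$data, s2$data)
  expect_equal(dim(s1$data)[4], 8)
  expect_equal(nrow(s1$poses), 8 * 32)
  # still regime: volumes identical up to noise
  v_sd <- apply(matrix(s1$data, ncol = 8), 1, stats::sd)
  expect_lt(stats::median(v_sd[phantom_blob$data > 1]),
            3 * 0.02 * mean(phantom_blob$data[phantom_blob$data > 0]))
})

test_that("correction reduces image error under sustained fast motion", {
  tm <- acq_timing(6, partitions_per_volume = 32)
  cfg <- motion_config("fast", duration = 6 * tm$volume_duration + 1,
                       baseline_still_volumes = 0, seed = 11)
  tr <- generate_trace(cfg)
  mask <- make_mask(phantom_blob, provenance = "phantom_support")
  rmse_mean <- function(pmc) {
    ser <- simulate_series(phantom_blob, tr, tm,
                           sim_config(pmc = pmc, pmc_latency = 1 / 80))
    mean(apply(ser$data, 4, phantom_rmse, phantom = phantom_blob,
               mask = mask$mask))
  }
  expect_lt(rmse_mean(TRUE), rmse_mean(FALSE))
})

test_that("image error rises with partition-weighted motion over an ensemble", {
  tm <- timing_1vol
  w <- partition_weights(phantom_blob)
  mask <- make_mask(phantom_blob, provenance = "phantom_support")$mask
  set.seed(21)
  res <- t(sapply(1:50, function(i) {
    t_on <- runif(1, 0, tm$volume_duration - 0.45)
    amp <- runif(1, 0.5, 6)
    tr <- burst_trace(tm$volume_duration + 0.3, t_on, 0.4,
                      amp = c(amp, 0, 0, 0, 0, 0))
    img <- simulate_volume(phantom_blob, tr, tm, sim_config())$image
    vm <- partition_weighted_motion(total_speed(tr), tm, w)
    c(mpw = vm$M_PW[1],
      rmse = phantom_rmse(img, phantom_blob, mask))
  }))
  expect_gt(stats::cor(res[, "mpw"], res[, "rmse"], method = "spearman"),
            0.7)
})

test_that("NIfTI round trip preserves data and voxel geometry", {
  tm <- acq_timing(3, partitions_per_volume = 32)
  tr <- const_trace(round(3 * tm$volume_duration * 80) + 10)
  ser <- simulate_series(phantom_blob, tr, tm, sim_config())
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_series(ser, f)
  back <- read_series(f)
  expect_equal(back$data, ser$data, tolerance = 1e-6)
  expect_equal(back$voxel_size, c(3, 3, 3))
  expect_equal(back$tr_volume, tm$volume_duration, tolerance = 1e-6)
})
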