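test_that("initial-volume discarding trims series and rejects overruns", {
  tm <- acq_timing(12, partitions_per_volume = 32)
  tr <- const_trace(round(12 * tm$volume_duration * 80) + 10)
  ser <- simulate_series(phantom_blob, tr, tm, sim_config())
  tr5 <- discard_initial(ser, 5)
  expect_equal(dim(tr5$data)[4], 7)
  expect_equal(min(tr5$poses$volume), 6)
  expect_identical(discard_initial(ser, 0), ser)
  expect_error(discard_initial(ser, 12), "cannot discard")

  arr <- array(rnorm(4 * 4 * 4 * 10), c(4, 4, 4, 10))
  expect_equal(dim(discard_initial(arr, 5))[4], 5)
})

test_that("realignment recovers known shifts to sub-voxel accuracy", {
  ph <- phantom_me
  # identical volumes: estimated poses are essentially zero
  ser0 <- array(rep(ph$data, 3), c(dim(ph$data), 3))
  ra0 <- realign(ser0, voxel_size = 3)
  expect_lt(max(abs(as.matrix(ra0$poses)[, 1:3])), 0.05 * 3)
  expect_lt(max(abs(as.matrix(ra0$poses)[, 4:6])), 0.05)

  # Fourier-shifted volume: recover a 2 mm translation within 0.1 voxel
  dd <- dim(ph$data)
  f <- function(nn) { k <- 0:(nn - 1); k[k >= nn / 2] <- k[k >= nn / 2] - nn; k }
  ramp <- outer(outer(exp(-2i * pi * f(dd[1]) * (2 / 3) / dd[1]),
                      rep(1 + 0i, dd[2])), rep(1 + 0i, dd[3]))
  shifted <- Re(stats::fft(stats::fft(ph$data) * ramp, inverse = TRUE) /
                  prod(dd))
  ser <- array(c(ph$data, shifted), c(dd, 2))
  ra <- realign(ser, voxel_size = 3)
  expect_equal(ra$poses$x[2], 2, tolerance = 0.3 / 2)  # 0.1 voxel of 3 mm
  expect_lt(max(abs(as.matrix(ra$poses)[2, 2:6])), 0.3)
})

test_that("realignment tracks simulated inter-volume motion", {
  tm <- acq_timing(6, partitions_per_volume = 32)
  set.seed(4)
  truth <- rbind(rep(0, 6),
                 cbind(matrix(runif(5 * 3, -3, 3), 5),
                       matrix(runif(5 * 3, -2, 2), 5)))
  n <- round(tm$volume_duration * 80 * 6) + 20
  tt <- (0:(n - 1)) / 80
  vol_of <- pmin(floor(tt / tm$volume_duration) + 1, 6)
  ch <- truth[vol_of, ]
  trc <- motion_trace(tt, ch[, 1], ch[, 2], ch[, 3], ch[, 4], ch[, 5],
                      ch[, 6], 80)
  ser <- simulate_series(phantom_me, trc, tm,
                         sim_config(noise_sd = 0.02, seed = 9))
  ra <- realign(ser)
  expect_gte(stats::cor(as.vector(as.matrix(ra$poses)), as.vector(truth)),
             0.9)
})

test_that("tSNR matches the known population ratio and ignores drift", {
  set.seed(8)
  d <- c(4, 4, 4)
  nv <- 95
  base <- array(rnorm(prod(d) * nv, mean = 100, sd = 10), c(d, nv))
  tsnr <- compute_tsnr(base)
  expect_equal(mean(tsnr), 10, tolerance = 1.5)
  # linear drift of 5 units across the series changes nothing material
  drift <- array(rep(seq(0, 5, length.out = nv), each = prod(d)), c(d, nv))
  tsnr_d <- compute_tsnr(base + drift)
  expect_equal(mean(tsnr_d), mean(tsnr), tolerance = 0.2)
  # constant series: infinite-tSNR sentinel, excluded from summaries
  const <- array(7, c(d, 5))
  expect_true(all(is.infinite(compute_tsnr(const))))
  m <- array(TRUE, d)
  expect_true(is.nan(mean_tsnr(compute_tsnr(const), m)))
  expect_error(compute_tsnr(base[, , , 1:2, drop = FALSE]), "3 volumes")
})

test_that("the motion-gated reference follows the threshold rule", {
  d <- c(6, 6, 6)
  vols <- array(0, c(d, 4))
  for (v in 1:4) vols[, , , v] <- v
  # baseline volume 1 has M_PW 2; others 8, 1.5, 2.0
  mpw <- c(2, 8, 1.5, 2.0)
  ref <- build_reference(vols, mpw, baseline = 1)
  expect_equal(sort(ref$indices), c(1, 3, 4))
  expect_equal(ref$reference[1, 1, 1], mean(c(1, 3, 4)))
  # all-equal M_PW: every volume contributes
  ref2 <- build_reference(vols, rep(1, 4), baseline = 1:2)
  expect_equal(ref2$indices, 1:4)
  expect_error(build_reference(vols, mpw, baseline = integer(0)),
               "non-empty")
})

test_that("mask construction covers support and thresholds monotonically", {
  m <- make_mask(phantom_blob, provenance = "phantom_support")
  support <- phantom_blob$data > 1e-6 * max(phantom_blob$data)
  expect_true(all(which(m$mask) %in% which(support)))
  expect_gt(m$n_voxels, 0)
  expect_error(make_mask(array(0, c(16, 16, 16))), "all-zero")

  m1 <- make_mask(phantom_me$data, threshold_frac = 0.1)
  m2 <- make_mask(phantom_me$data, threshold_frac = 0.2)
  expect_lte(m2$n_voxels, m1$n_voxels)
})

test_that("RMSE is computed on the mean-scaled data and scale invariant", {
  d <- dim(phantom_me$data)
  mask <- make_mask(phantom_me, provenance = "phantom_support")
  ref <- phantom_me$data
  ser <- array(0, c(d, 3))
  ser[, , , 1] <- ref
  ser[, , , 2] <- ref
  ser[, , , 3] <- ref
  out <- scale_and_rmse(ser, ref, mask)
  expect_equal(out$rmse$rmse, rep(0, 3))

  # adding a constant 0.1 (in scaled units) inside the mask
  sc <- out$scale
  ser2 <- ser
  v2 <- ser2[, , , 2]
  v2[mask$mask] <- v2[mask$mask] + 0.1 * sc
  ser2[, , , 2] <- v2
  out2 <- scale_and_rmse(ser2, ref, mask)
  # the added offset also raises the global scale by (1 + 0.1/3), giving
  # exactly 0.1 / (1 + 0.1/3) in rescaled units
  expect_equal(out2$rmse$rmse[2], 0.1 / (1 + 0.1 / 3), tolerance = 1e-6)

  out3 <- scale_and_rmse(ser2 * 2, ref * 2, mask)
  expect_equal(out3$rmse$rmse, out2$rmse$rmse)
})
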