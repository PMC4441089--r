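test_that("low-pass filter has unit DC gain and the designed rolloff", {
  tr <- const_trace(800, pose = c(3.3, -2, 1, 0.5, 0, 4))
  lp <- lowpass(tr, 10)
  expect_lt(max(abs(lp$x - 3.3)), 1e-6)
  expect_lt(max(abs(lp$yaw - 4)), 1e-6)

  # oracle: measured attenuation of a sinusoid matches the filter's
  # theoretical two-pass magnitude response
  tt <- (0:3199) / 80
  mk <- function(f) motion_trace(tt, sin(2 * pi * f * tt), tt * 0, tt * 0,
                                 tt * 0, tt * 0, tt * 0, 80)
  bf <- signal::butter(5, 10 / 40, type = "low")
  H <- function(f) {
    z <- exp(1i * 2 * pi * f / 80)
    Mod(sum(bf$b * z^-(0:(length(bf$b) - 1))) /
          sum(bf$a * z^-(0:(length(bf$a) - 1))))^2  # two passes
  }
  mid <- 500:2700
  a128 <- max(abs(lowpass(mk(12.8), 10)$x[mid]))
  expect_equal(a128, H(12.8), tolerance = 0.15)
  expect_gte(-20 * log10(a128), 20)   # >= 20 dB down at the vibration line
  a1 <- max(abs(lowpass(mk(1), 10)$x[mid]))
  expect_equal(a1, 1, tolerance = 0.05)
  expect_error(lowpass(const_trace(100), 40), "Nyquist")
})

test_that("total speed reproduces single-channel and Pythagorean cases", {
  n <- 400
  tt <- (0:(n - 1)) / 80
  z0 <- rep(0, n)
  expect_equal(max(total_speed(const_trace(n, c(1, 2, 3, 4, 5, 6)))$S), 0)
  # pure x at 2 mm/s
  s <- total_speed(motion_trace(tt, 2 * tt, z0, z0, z0, z0, z0, 80))$S
  expect_equal(s, rep(2, n))
  # pure yaw at 1 deg/s: unit weight, i.e. a 180/pi mm ~ 5.7 cm radius
  s <- total_speed(motion_trace(tt, z0, z0, z0, z0, z0, tt, 80))$S
  expect_equal(s, rep(1, n))
  # 3-4-5
  s <- total_speed(motion_trace(tt, 3 * tt, 4 * tt, z0, z0, z0, z0, 80))$S
  expect_equal(s, rep(5, n))
  expect_error(total_speed(const_trace(1)), "2 samples")
})

test_that("total speed is invariant to sign flips of any channel", {
  cfg <- motion_config("fast", duration = 20, baseline_still_volumes = 0,
                       seed = 5)
  tr <- generate_trace(cfg)
  s0 <- total_speed(tr)$S
  for (ch in c("x", "pitch", "yaw")) {
    tr2 <- tr
    tr2[[ch]] <- -tr2[[ch]]
    expect_equal(total_speed(tr2)$S, s0)
  }
})

test_that("integrated motion is the time integral over each volume", {
  tm <- acq_timing(2, tr = 0.078, partitions_per_volume = 44)
  n <- 600
  sp <- structure(list(times = (0:(n - 1)) / 80, S = rep(1, n), dt = 1 / 80),
                  class = "speed_series")
  vm <- integrated_motion(sp, tm)
  expect_equal(vm$M, rep(tm$volume_duration, 2), tolerance = 1 / 80 / 3.4)
  sp$S <- rep(0, n)
  expect_equal(integrated_motion(sp, tm)$M, c(0, 0))
  # piecewise: S = 1 in the first half of volume 1 only
  sp$S <- as.numeric(sp$times < tm$volume_duration / 2)
  vm <- integrated_motion(sp, tm)
  expect_equal(vm$M[1], tm$volume_duration / 2, tolerance = 1 / 80)
  # uncovered acquisition names the first missing volume
  short <- structure(list(times = (0:99) / 80, S = rep(1, 100), dt = 1 / 80),
                     class = "speed_series")
  expect_error(integrated_motion(short, tm), "volume 1")
})

test_that("metrics are invariant to a constant pose offset", {
  cfg <- motion_config("slow", duration = 30, baseline_still_volumes = 0,
                       vibration_amplitude = 0, noise_sd = 0, seed = 9)
  tr <- generate_trace(cfg)
  tr2 <- tr
  tr2$x <- tr2$x + 4
  tr2$yaw <- tr2$yaw - 2
  tm <- acq_timing(8, partitions_per_volume = 32)
  w <- partition_weights(phantom_blob)
  v1 <- partition_weighted_motion(total_speed(tr), tm, w)
  v2 <- partition_weighted_motion(total_speed(tr2), tm, w)
  expect_equal(v2$M, v1$M)
  expect_equal(v2$M_PW, v1$M_PW)
})

test_that("partition weights reflect the k-space energy distribution", {
  # delta at the grid centre transforms to constant magnitude
  delta <- array(0, c(32, 32, 32))
  delta[17, 17, 17] <- 1
  k <- partition_weights(delta)$k
  expect_equal(k, rep(1, 32), tolerance = 1e-10)

  # Gaussian blob: maximal at the k_z = 0 plane, monotone to the edges
  k <- partition_weights(phantom_blob)$k
  expect_equal(which.max(k), 17)
  expect_true(all(diff(k[1:17]) >= 0))
  expect_true(all(diff(k[17:32]) <= 0))

  # global intensity scale leaves normalized weights unchanged
  sc <- phantom_blob$data * 7.3
  expect_equal(partition_weights(sc)$k, k)

  expect_equal(mean(partition_weights(phantom_me)$k), 1, tolerance = 1e-12)
  expect_error(partition_weights(array(0, c(16, 16, 16))), "all-zero")
})

test_that("partition weighting reduces to plain integration when uniform", {
  cfg <- motion_config("fast", duration = 40, baseline_still_volumes = 0,
                       seed = 2)
  sp <- total_speed(lowpass(generate_trace(cfg), 10))
  tm <- acq_timing(11, partitions_per_volume = 44)
  vm <- partition_weighted_motion(sp, tm, uniform_weights(44))
  expect_lt(max(abs(vm$M_PW - vm$M)), 1e-9)
  expect_error(partition_weighted_motion(sp, tm, uniform_weights(32)),
               "does not match")
})

test_that("motion confined to a zero-weight partition scores zero M_PW", {
  tm <- timing_1vol
  # burst inside excitation slot 5 (plane 5, ascending order)
  t_on <- 4 * tm$tr + 0.005
  tr <- burst_trace(tm$volume_duration + 0.2, t_on, 0.06)
  sp <- total_speed(tr)
  w <- uniform_weights(32)
  w$k[5] <- 0
  vm <- partition_weighted_motion(sp, tm, w)
  # all nonzero speed lies in slot 5 except edge samples of the derivative
  expect_lt(vm$M_PW[1], 0.02 * vm$M[1])
})

test_that("central-partition motion scores higher M_PW than peripheral", {
  tm <- timing_1vol
  w <- partition_weights(phantom_blob)
  mk <- function(t_on) total_speed(burst_trace(tm$volume_duration + 0.3,
                                               t_on, 0.4))
  center <- partition_weighted_motion(mk((17 - 1) * tm$tr), tm, w)
  periph <- partition_weighted_motion(mk(0.05), tm, w)
  expect_gt(center$M_PW[1], periph$M_PW[1])
  expect_equal(center$M[1], periph$M[1], tolerance = 0.01)
})
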