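# shared fixtures, built in code at load time (all small)

# constant-pose trace covering n samples at fs Hz
const_trace <- function(n, pose = rep(0, 6), fs = 80) {
  rep1 <- function(v) rep(v, n)
  motion_trace((seq_len(n) - 1) / fs, rep1(pose[1]), rep1(pose[2]),
               rep1(pose[3]), rep1(pose[4]), rep1(pose[5]), rep1(pose[6]),
               fs)
}

# trace with a single raised-cosine burst on given channels
burst_trace <- function(duration, t_on, burst_dur, amp = c(5, 0, 0, 0, 0, 0),
                        fs = 80) {
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  prof <- ifelse(tt >= t_on & tt < t_on + burst_dur,
                 (1 - cos(2 * pi * (tt - t_on) / burst_dur)) / 2, 0)
  motion_trace(tt, amp[1] * prof, amp[2] * prof, amp[3] * prof,
               amp[4] * prof, amp[5] * prof, amp[6] * prof, fs)
}

# small reusable phantoms (32 partitions so timing matches the 3rd axis)
phantom_blob <- make_phantom(c(32, 32, 32), "gaussian_blob", voxel_size = 3)
phantom_me <- make_phantom(c(32, 32, 32), "multi_ellipsoid", voxel_size = 3,
                           seed = 2)

# timing for one 32-partition volume at the standard TR
timing_1vol <- acq_timing(1, tr = 0.078, partitions_per_volume = 32)

# masked RMSE of an image against the phantom truth
phantom_rmse <- function(img, phantom, mask = NULL) {
  if (is.null(mask))
    mask <- make_mask(phantom, provenance = "phantom_support")$mask
  sqrt(mean((img[mask] - phantom$data[mask])^2))
}
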