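#' Zero-phase low-pass filter a motion trace
#'
#' Removes mechanical vibration and tracker noise above `cutoff` Hz from all
#' six pose channels before the speed metrics are computed. In 3D EPI the
#' dominant vibration sits at the partition repetition frequency (12.8 Hz
#' for a 78 ms TR), so a 10 Hz cutoff separates it cleanly from
#' physiological head motion. A Butterworth filter is applied forward and
#' backward (zero phase) so that motion events keep their alignment with
#' the partition-encoding timeline; each channel is reflection-padded and
#' mean-centred before filtering to suppress start-up transients, giving a
#' DC gain of exactly 1.
#'
#' @param trace A [motion_trace()].
#' @param cutoff Cutoff frequency in Hz, below Nyquist.
#' @param order Butterworth order for each pass (default 5, which puts the
#'   12.8 Hz vibration line about 25 dB down after the two passes while
#'   leaving sub-2 Hz head motion untouched; the effective magnitude
#'   response is squared by the forward-backward application).
#' @return The filtered `motion_trace`.
#' @export
lowpass <- function(trace, cutoff = 10, order = 5) {
  validate_motion_trace(trace)
  fs <- trace$sampling_rate
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must lie in (0, Nyquist) = (0, ", fs / 2, ") Hz")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  n <- length(trace$times)
  pad <- min(n - 1, max(32L, ceiling(3 * fs / cutoff)))
  for (ch in trace_channels) {
    x <- trace[[ch]]
    mu <- mean(x)
    xc <- x - mu
    # odd (antisymmetric) reflection about both endpoints
    head_pad <- 2 * xc[1] - xc[seq(pad + 1, 2)]
    tail_pad <- 2 * xc[n] - xc[seq(n - 1, n - pad)]
    y <- signal::filtfilt(bf, c(head_pad, xc, tail_pad))
    trace[[ch]] <- y[seq(pad + 1, pad + n)] + mu
  }
  trace
}

#' Total speed of a 6-DOF motion trace
#'
#' Collapses the six pose channels into a single rate-of-motion series: the
#' root-sum-square of the time derivatives of the three translations
#' (mm) and three rotations (degrees),
#' \deqn{S = \sqrt{\dot x^2 + \dot y^2 + \dot z^2 + \dot P^2 + \dot R^2 +
#'   \dot Y^2}.}
#' Weighting degrees equally with millimetres is equivalent to assuming a
#' rotational radius of 5.7 cm (180/pi mm), a reasonable effective radius
#' for the head. Derivatives use central differences with one-sided
#' differences at the ends, so the series keeps the camera's temporal
#' resolution and length.
#'
#' @param trace A [motion_trace()], normally after [lowpass()].
#' @return An object of class `speed_series`: list with `times`, `S`
#'   (mm-equivalent/s) and `dt` (s).
#' @export
total_speed <- function(trace) {
  validate_motion_trace(trace)
  n <- length(trace$times)
  if (n < 2) stop("total_speed needs at least 2 samples")
  dt <- 1 / trace$sampling_rate
  ss <- numeric(n)
  for (ch in trace_channels) {
    d <- channel_derivative(trace[[ch]], dt)
    ss <- ss + d^2
  }
  structure(list(times = trace$times, S = sqrt(ss), dt = dt),
            class = "speed_series")
}

# central differences, one-sided at the ends (second-order interior)
channel_derivative <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Acquisition timing of a multi-shot 3D EPI sequence
#'
#' Maps every RF excitation (one k_x-k_y partition plane per TR) to a time
#' interval. With the default linearly ascending partition encoding the
#' m-th excitation of a volume acquires k_z plane `partition_order[m]`,
#' planes being numbered 1..P from the most negative k_z so that the
#' k_z = 0 plane sits at `floor(P/2) + 1`.
#'
#' @param n_volumes Number of image volumes.
#' @param tr Repetition time between excitations in seconds (default
#'   0.078).
#' @param partitions_per_volume Number of partitions (RF excitations) per
#'   volume (default 44, giving a 3.432 s volume).
#' @param start_time Trace time of the first excitation in seconds
#'   (default 0).
#' @param partition_order Permutation of `1:partitions_per_volume` giving
#'   the k_z plane acquired at each successive excitation (default
#'   ascending).
#' @return An object of class `acq_timing`.
#' @export
acq_timing <- function(n_volumes, tr = 0.078, partitions_per_volume = 44,
                       start_time = 0, partition_order = NULL) {
  if (tr <= 0 || partitions_per_volume < 1 || n_volumes < 1)
    stop("tr, partitions_per_volume and n_volumes must be positive")
  if (is.null(partition_order)) partition_order <- seq_len(partitions_per_volume)
  if (!setequal(partition_order, seq_len(partitions_per_volume)) ||
      length(partition_order) != partitions_per_volume)
    stop("partition_order must be a permutation of 1:", partitions_per_volume)
  structure(list(n_volumes = as.integer(n_volumes), tr = tr,
                 partitions_per_volume = as.integer(partitions_per_volume),
                 volume_duration = tr * partitions_per_volume,
                 start_time = start_time,
                 partition_order = as.integer(partition_order),
                 center_partition_index =
                   floor(partitions_per_volume / 2) + 1L),
            class = "acq_timing")
}

#' @export
print.acq_timing <- function(x, ...) {
  cat("<acq_timing> ", x$n_volumes, " volumes x ", x$partitions_per_volume,
      " partitions @ TR ", x$tr * 1000, " ms (",
      signif(x$volume_duration, 4), " s/volume)\n", sep = "")
  invisible(x)
}

# For each speed sample, the (volume, excitation slot, k_z plane) it falls
# in, or NA outside the acquisition. Half-open [start, start + TR) slots
# tile each volume window exactly.
assign_samples <- function(times, timing) {
  rel <- times - timing$start_time
  vol <- floor(rel / timing$volume_duration) + 1
  slot <- floor((rel %% timing$volume_duration) / timing$tr) + 1
  slot <- pmin(slot, timing$partitions_per_volume)  # guard fp edge
  ok <- rel >= 0 & vol >= 1 & vol <= timing$n_volumes
  vol[!ok] <- NA_integer_
  slot[!ok] <- NA_integer_
  plane <- ifelse(is.na(slot), NA_integer_, timing$partition_order[slot])
  list(volume = as.integer(vol), slot = as.integer(slot),
       plane = as.integer(plane))
}

check_coverage <- function(speed, timing) {
  vol_end <- timing$start_time +
    seq_len(timing$n_volumes) * timing$volume_duration
  last <- max(speed$times)
  uncovered <- which(vol_end - speed$dt > last + 1e-9)
  if (length(uncovered) > 0)
    stop("speed series does not cover the acquisition window of volume ",
         uncovered[1])
  invisible(TRUE)
}

#' Integrated motion per image volume
#'
#' Numerically integrates the total speed over the acquisition window of
#' each image volume: \eqn{M_v = \sum_i S_i \Delta t} over the speed
#' samples falling in volume v. The result is a single mm-equivalent scalar
#' per volume, insensitive to a constant pose offset (only derivatives
#' enter).
#'
#' @param speed A `speed_series` from [total_speed()].
#' @param timing An [acq_timing()].
#' @return An object of class `volume_motion`: data frame with
#'   `volume_index` and `M` (and `M_PW` once
#'   [partition_weighted_motion()] has been used).
#' @export
integrated_motion <- function(speed, timing) {
  if (!inherits(speed, "speed_series")) stop("speed must be a speed_series")
  check_coverage(speed, timing)
  a <- assign_samples(speed$times, timing)
  keep <- !is.na(a$volume)
  m <- vapply(seq_len(timing$n_volumes), function(v)
    sum(speed$S[keep][a$volume[keep] == v]) * speed$dt, numeric(1))
  structure(data.frame(volume_index = seq_len(timing$n_volumes), M = m),
            class = c("volume_motion", "data.frame"))
}

#' k-space partition energy weights from a reference volume
#'
#' Motion hurts image quality most when it coincides with the acquisition
#' of the energetic central k-space partitions. The weights quantify this:
#' the reference magnitude image is Fourier transformed and the squared
#' modulus summed over each k_x-k_y plane,
#' \eqn{k_j = \sum_{k_x}\sum_{k_y} |c|^2}. Because the transform is taken
#' of the magnitude image an artificial conjugate symmetry is imposed on
#' k-space; this changes the weights by a few percent relative to raw
#' multi-channel data and is accepted. Planes are returned in ascending
#' k_z order (k_z = 0 at index `floor(P/2) + 1`), matching
#' [acq_timing()]'s plane numbering.
#'
#' @param reference 3D numeric array (magnitude image), or a `phantom`.
#' @param partition_axis Array axis of the partition (slow phase-encode)
#'   direction; default 3.
#' @param normalization `"mean_one"` (default; weights scaled to mean 1 so
#'   the partition-weighted motion metric stays on the same mm-equivalent
#'   scale as the unweighted one), `"sum_one"`, or `"raw"`.
#' @return An object of class `partition_weights`: list with `k`,
#'   `normalization`, `partition_axis`.
#' @export
partition_weights <- function(reference, partition_axis = 3,
                              normalization = c("mean_one", "sum_one", "raw")) {
  normalization <- match.arg(normalization)
  if (inherits(reference, "phantom")) {
    partition_axis <- reference$partition_axis
    reference <- reference$data
  }
  if (length(dim(reference)) != 3) stop("reference must be a 3D array")
  if (all(reference == 0)) stop("all-zero reference image: weights undefined")
  K <- fftshift(stats::fft(reference))
  e <- Mod(K)^2
  k <- apply(e, partition_axis, sum)
  k <- switch(normalization,
              mean_one = k / mean(k),
              sum_one = k / sum(k),
              raw = k)
  structure(list(k = k, normalization = normalization,
                 partition_axis = partition_axis),
            class = "partition_weights")
}

#' Uniform partition weights
#'
#' Convenience constructor for weights that are all equal (mean-one), under
#' which the partition-weighted integrated motion reduces exactly to the
#' plain integrated motion.
#'
#' @param n Number of partitions.
#' @export
uniform_weights <- function(n) {
  structure(list(k = rep(1, n), normalization = "mean_one",
                 partition_axis = 3L),
            class = "partition_weights")
}

#' Partition-weighted integrated motion per image volume
#'
#' As [integrated_motion()], but each speed sample is weighted by the
#' k-space energy weight of the partition being acquired at that moment:
#' \eqn{M_{PW,v} = \sum_j \sum_i S_{i,j}\, k_j\, \Delta t}, with the inner
#' sum over speed samples falling in partition j of volume v. Motion during
#' the energetic central partitions is thereby up-weighted relative to
#' motion during the k-space periphery. With uniform mean-one weights
#' `M_PW` equals `M` exactly.
#'
#' @param speed A `speed_series`.
#' @param timing An [acq_timing()].
#' @param weights A [partition_weights()] whose length equals
#'   `timing$partitions_per_volume`.
#' @return A `volume_motion` data frame with columns `volume_index`, `M`
#'   and `M_PW`.
#' @export
partition_weighted_motion <- function(speed, timing, weights) {
  if (!inherits(weights, "partition_weights"))
    stop("weights must be a partition_weights object")
  if (length(weights$k) != timing$partitions_per_volume)
    stop("weights length ", length(weights$k), " does not match ",
         timing$partitions_per_volume, " partitions per volume")
  vm <- integrated_motion(speed, timing)
  a <- assign_samples(speed$times, timing)
  keep <- !is.na(a$volume)
  w <- weights$k[a$plane[keep]]
  sw <- speed$S[keep] * w
  vols <- a$volume[keep]
  mpw <- vapply(seq_len(timing$n_volumes), function(v)
    sum(sw[vols == v]) * speed$dt, numeric(1))
  vm$M_PW <- mpw
  vm
}
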