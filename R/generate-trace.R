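#' Configuration for synthetic motion-trace generation
#'
#' Describes one of three motion regimes used in PMC validation experiments:
#' `"none"` (subject lies still), `"slow"` (deliberate slow head movements,
#' peak combined speed 10-15 mm-equivalent/s) and `"fast"` (fast movements,
#' 40-50 mm-equivalent/s). Movement bursts are interspersed with periods of
#' stillness, the marker excursion is coached to stay within +/- 10 mm and
#' +/- 5 degrees, and the first `baseline_still_volumes` image volumes are
#' motion-free so that an artifact-free reference can be built.
#'
#' Rotations are expressed in degrees and weighted equally with mm of
#' translation throughout (equivalent to a 5.7 cm rotational radius), so
#' "mm-equivalent" speeds combine all six channels.
#'
#' @param regime One of `"none"`, `"slow"`, `"fast"`.
#' @param duration Trace duration in seconds.
#' @param sampling_rate Camera frame rate in Hz (default 80).
#' @param amplitude_bound_trans Bound on each translation channel in mm
#'   (default 10).
#' @param amplitude_bound_rot Bound on each rotation channel in degrees
#'   (default 5).
#' @param peak_speed_range Range (length 2) the peak combined 6-DOF speed of
#'   each burst is drawn from, mm-equivalent/s. Defaults: `c(10, 15)` for
#'   slow, `c(40, 50)` for fast.
#' @param burst_rate Mean movement-burst rate in bursts/minute. Defaults:
#'   10 (slow), 12 (fast), 0 (none).
#' @param burst_duration Nominal burst duration in seconds (each burst draws
#'   its duration within +/- 15% of this). Defaults: 1.8 (slow),
#'   0.75 (fast).
#' @param still_fraction Minimum fraction of the trace that must remain
#'   still; burst onsets are thinned once the moving-time budget
#'   `(1 - still_fraction) * duration` is exhausted. Default 0.6.
#' @param baseline_still_volumes Number of initial image volumes kept
#'   motion-free (default 12).
#' @param volume_duration Duration of one image volume in seconds, used only
#'   to convert `baseline_still_volumes` to a time (default 3.432 = 44
#'   partitions x 78 ms).
#' @param vibration_freq Scanner vibration frequency in Hz (default 12.8,
#'   the partition repetition frequency of a 78 ms TR sequence).
#' @param vibration_amplitude Vibration amplitude in mm (default 0.05).
#' @param noise_sd Gaussian tracker noise SD applied to all six channels
#'   (mm / deg; default 0.015, emulating the sub-0.1 mm precision of an
#'   optical Moire-marker camera plus residual unmodelled jitter; after
#'   10 Hz low-pass filtering this floor integrates to roughly 2
#'   mm-equivalent of M_PW per 3.4 s volume, the level still subjects
#'   show).
#' @param seed Integer seed for reproducible generation.
#'
#' @return An object of class `motion_regime_config`.
#' @export
motion_config <- function(regime = c("none", "slow", "fast"),
                          duration = 340,
                          sampling_rate = 80,
                          amplitude_bound_trans = 10,
                          amplitude_bound_rot = 5,
                          peak_speed_range = NULL,
                          burst_rate = NULL,
                          burst_duration = NULL,
                          still_fraction = 0.6,
                          baseline_still_volumes = 12,
                          volume_duration = 3.432,
                          vibration_freq = 12.8,
                          vibration_amplitude = 0.05,
                          noise_sd = 0.015,
                          seed = NULL) {
  regime <- match.arg(regime)
  if (!is.finite(duration) || duration <= 0) stop("duration must be positive")
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  defaults <- switch(regime,
    none = list(speed = c(0, 0), rate = 0, dur = 0),
    slow = list(speed = c(10, 15), rate = 10, dur = 1.8),
    fast = list(speed = c(40, 50), rate = 12, dur = 0.75))
  if (is.null(peak_speed_range)) peak_speed_range <- defaults$speed
  if (is.null(burst_rate)) burst_rate <- defaults$rate
  if (is.null(burst_duration)) burst_duration <- defaults$dur
  if (regime != "none") {
    baseline_s <- baseline_still_volumes * volume_duration
    if (baseline_s > duration)
      stop("baseline-still period (", baseline_s,
           " s) exceeds trace duration (", duration, " s)")
  }
  structure(list(regime = regime, duration = duration,
                 sampling_rate = sampling_rate,
                 amplitude_bound_trans = amplitude_bound_trans,
                 amplitude_bound_rot = amplitude_bound_rot,
                 peak_speed_range = peak_speed_range,
                 burst_rate = burst_rate, burst_duration = burst_duration,
                 still_fraction = still_fraction,
                 baseline_still_volumes = baseline_still_volumes,
                 volume_duration = volume_duration,
                 vibration_freq = vibration_freq,
                 vibration_amplitude = vibration_amplitude,
                 noise_sd = noise_sd, seed = seed),
            class = "motion_regime_config")
}

#' Generate a camera-like 6-DOF motion trace
#'
#' Produces a synthetic tracker trace with the structure assumed by PMC
#' validation experiments: a motion-free baseline period, raised-cosine
#' (Hann-windowed) pose excursions on randomly selected channels whose peak
#' combined 6-DOF speed falls inside the configured range, Poisson burst
#' onsets thinned to respect the still-time budget, additive sinusoidal
#' scanner vibration on the translations, and white tracker noise.
#'
#' Each burst moves out and back to the baseline pose, so channel bounds
#' never accumulate across bursts. Amplitude is distributed over three
#' translation channels plus (usually) one rotation channel and clipped
#' channel-wise to the configured bounds by redistributing the clipped
#' energy, preserving the drawn peak speed.
#'
#' @param config A [motion_config()] object.
#' @return A [motion_trace()].
#' @export
generate_trace <- function(config) {
  if (!inherits(config, "motion_regime_config"))
    stop("config must be created by motion_config()")
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$sampling_rate
  n <- round(config$duration * fs)
  if (n < 2) stop("duration too short for the given sampling rate")
  times <- (seq_len(n) - 1) / fs
  ch <- matrix(0, nrow = n, ncol = 6,
               dimnames = list(NULL, trace_channels))

  if (config$regime != "none" && config$burst_rate > 0) {
    t_min <- config$baseline_still_volumes * config$volume_duration
    budget <- (1 - config$still_fraction) * config$duration
    moving <- 0
    t_cur <- t_min
    rate_s <- config$burst_rate / 60
    repeat {
      gap <- stats::rexp(1, rate_s)
      dur <- config$burst_duration * stats::runif(1, 0.85, 1.15)
      t_on <- t_cur + gap
      if (t_on + dur > config$duration) break
      if (moving + dur <= budget) {
        amp <- draw_burst_amplitudes(config, dur)
        sel <- times >= t_on & times < t_on + dur
        if (any(sel)) {
          prof <- (1 - cos(2 * pi * (times[sel] - t_on) / dur)) / 2
          ch[sel, ] <- ch[sel, ] + outer(prof, amp)
        }
        moving <- moving + dur
      }
      t_cur <- t_on + dur
    }
  }

  if (config$noise_sd > 0)
    ch <- ch + matrix(stats::rnorm(6 * n, sd = config$noise_sd), n, 6)

  vib_phase <- if (config$vibration_amplitude > 0) stats::runif(1, 0, 2 * pi) else 0
  tr <- motion_trace(times, ch[, 1], ch[, 2], ch[, 3],
                     ch[, 4], ch[, 5], ch[, 6], fs)
  if (config$vibration_amplitude > 0)
    tr <- add_vibration(tr, config$vibration_freq,
                        config$vibration_amplitude, vib_phase)
  # the coached amplitude range is a hard constraint (volunteers watched
  # their own traces in real time); clip the tails of noise + vibration
  for (i in 1:3) {
    b <- config$amplitude_bound_trans
    tr[[trace_channels[i]]] <- pmin(pmax(tr[[trace_channels[i]]], -b), b)
  }
  for (i in 4:6) {
    b <- config$amplitude_bound_rot
    tr[[trace_channels[i]]] <- pmin(pmax(tr[[trace_channels[i]]], -b), b)
  }
  tr
}

# Draw the per-channel peak amplitudes of one raised-cosine burst.
# A burst of duration T with channel amplitudes A_c has combined peak speed
# pi * ||A|| / T, so ||A|| = s_peak * T / pi fixes the drawn peak speed.
# Amplitude is spread over the three translations plus, with probability
# 0.6, one rotation channel; channels violating their bound are clipped and
# the removed norm is redistributed over the remaining channels, which is
# always feasible because sqrt(3) * amplitude_bound_trans exceeds the
# largest ||A|| any admissible (speed, duration) pair can request.
draw_burst_amplitudes <- function(config, dur) {
  s_peak <- stats::runif(1, config$peak_speed_range[1],
                         config$peak_speed_range[2])
  L <- s_peak * dur / pi
  w <- c(stats::runif(3, 0.2, 1), 0, 0, 0)
  if (stats::runif(1) < 0.6)
    w[3 + sample.int(3, 1)] <- stats::runif(1, 0.1, 0.4)
  sgn <- sample(c(-1, 1), 6, replace = TRUE)
  a <- sgn * w / sqrt(sum(w^2)) * L
  # headroom so vibration and noise riding on a full burst stay in bounds
  head <- config$vibration_amplitude + 3 * config$noise_sd
  bounds <- c(rep(config$amplitude_bound_trans - head, 3),
              rep(config$amplitude_bound_rot - 3 * config$noise_sd, 3))
  clipped <- rep(FALSE, 6)
  for (iter in 1:6) {
    over <- abs(a) > bounds + 1e-12
    if (!any(over)) break
    clipped <- clipped | over
    a[clipped] <- sign(a[clipped]) * bounds[clipped]
    free <- !clipped & a != 0
    resid2 <- L^2 - sum(a[clipped]^2)
    if (resid2 <= 0 || !any(free)) break
    a[free] <- a[free] * sqrt(resid2 / sum(a[free]^2))
  }
  a
}
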