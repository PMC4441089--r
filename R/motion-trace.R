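#' Six degree-of-freedom motion trace
#'
#' Container for a time-stamped rigid-body pose series as produced by an
#' in-bore optical tracking camera: three translations in mm (`x`, `y`, `z`)
#' and three rotations in degrees (`pitch`, `roll`, `yaw`), sampled nominally
#' uniformly at `sampling_rate` Hz.
#'
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param x,y,z Translations in mm, same length as `times`.
#' @param pitch,roll,yaw Rotations in degrees, same length as `times`.
#' @param sampling_rate Nominal sampling rate in Hz. The median inter-sample
#'   interval must agree with `1/sampling_rate` to within 1%.
#'
#' @return An object of class `motion_trace`: a list with the seven channel
#'   vectors and the sampling rate.
#' @export
motion_trace <- function(times, x, y, z, pitch, roll, yaw, sampling_rate) {
  tr <- structure(
    list(times = as.numeric(times),
         x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
         pitch = as.numeric(pitch), roll = as.numeric(roll),
         yaw = as.numeric(yaw),
         sampling_rate = as.numeric(sampling_rate)),
    class = "motion_trace")
  validate_motion_trace(tr)
  tr
}

trace_channels <- c("x", "y", "z", "pitch", "roll", "yaw")

validate_motion_trace <- function(tr) {
  n <- length(tr$times)
  for (ch in trace_channels) {
    if (length(tr[[ch]]) != n)
      stop("channel '", ch, "' has length ", length(tr[[ch]]),
           " but times has length ", n)
  }
  if (n >= 2 && any(diff(tr$times) <= 0))
    stop("times must be strictly increasing")
  if (!is.finite(tr$sampling_rate) || tr$sampling_rate <= 0)
    stop("sampling_rate must be positive")
  if (n >= 2) {
    med <- stats::median(diff(tr$times))
    if (abs(med - 1 / tr$sampling_rate) > 0.01 / tr$sampling_rate)
      stop("median inter-sample interval ", signif(med, 6),
           " is inconsistent with sampling_rate ", tr$sampling_rate, " Hz")
  }
  invisible(tr)
}

#' @export
print.motion_trace <- function(x, ...) {
  cat("<motion_trace> ", length(x$times), " samples @ ", x$sampling_rate,
      " Hz (", signif(diff(range(x$times)), 4), " s)\n", sep = "")
  rng <- sapply(trace_channels, function(ch) range(x[[ch]]))
  cat("  translations [mm]:  x ", fmt_rng(rng[, "x"]), "  y ",
      fmt_rng(rng[, "y"]), "  z ", fmt_rng(rng[, "z"]), "\n", sep = "")
  cat("  rotations   [deg]:  P ", fmt_rng(rng[, "pitch"]), "  R ",
      fmt_rng(rng[, "roll"]), "  Y ", fmt_rng(rng[, "yaw"]), "\n", sep = "")
  invisible(x)
}

fmt_rng <- function(r) paste0("[", signif(r[1], 3), ", ", signif(r[2], 3), "]")

#' @export
as.data.frame.motion_trace <- function(x, ...) {
  data.frame(time_s = x$times, x_mm = x$x, y_mm = x$y, z_mm = x$z,
             pitch_deg = x$pitch, roll_deg = x$roll, yaw_deg = x$yaw)
}

#' Number of samples in a motion trace
#' @param x A `motion_trace`.
#' @export
length.motion_trace <- function(x) length(x$times)

log_columns <- c("time_s", "x_mm", "y_mm", "z_mm",
                 "pitch_deg", "roll_deg", "yaw_deg")

#' Write a motion trace as a tracker log
#'
#' Tracker logs are tab-delimited text with one header line and columns
#' `time_s, x_mm, y_mm, z_mm, pitch_deg, roll_deg, yaw_deg`.
#'
#' @param trace A `motion_trace`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_log <- function(trace, path) {
  validate_motion_trace(trace)
  df <- as.data.frame(trace)
  names(df) <- log_columns
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tracker log
#'
#' @param path Path to a log written by [write_log()] (or by the PMC logging
#'   system in the same format).
#' @param sampling_rate Optional sampling rate in Hz; if `NULL` it is
#'   inferred from the median inter-sample interval.
#' @return A `motion_trace`.
#' @export
read_log <- function(path, sampling_rate = NULL) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (!identical(header, log_columns))
    stop("malformed header in '", path, "': expected columns ",
         paste(log_columns, collapse = ", "))
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad) > 0)
    stop("non-monotone time column in '", path, "' at line ",
         bad[1] + 2L, " (data row ", bad[1] + 1L, ")")
  if (is.null(sampling_rate))
    sampling_rate <- 1 / stats::median(diff(df$time_s))
  motion_trace(df$time_s, df$x_mm, df$y_mm, df$z_mm,
               df$pitch_deg, df$roll_deg, df$yaw_deg, sampling_rate)
}

#' Add a sinusoidal vibration to the translation channels
#'
#' Models mechanical scanner vibration, which in 3D EPI appears at the
#' partition repetition frequency (1/TR, 12.8 Hz for a 78 ms TR). The
#' sinusoid is added to the three translation channels only; rotations are
#' left untouched.
#'
#' @param trace A `motion_trace`.
#' @param freq Vibration frequency in Hz; must be below the Nyquist
#'   frequency `sampling_rate / 2`.
#' @param amplitude Peak amplitude in mm.
#' @param phase Phase offset in radians (default 0).
#' @return The trace with vibration added.
#' @export
add_vibration <- function(trace, freq, amplitude, phase = 0) {
  validate_motion_trace(trace)
  if (freq <= 0 || freq >= trace$sampling_rate / 2)
    stop("vibration frequency must lie below Nyquist: (0, ",
         trace$sampling_rate / 2, ") Hz")
  if (amplitude == 0) return(trace)
  s <- amplitude * sin(2 * pi * freq * trace$times + phase)
  trace$x <- trace$x + s
  trace$y <- trace$y + s
  trace$z <- trace$z + s
  trace
}
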