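# k-space helpers. Arrays are stored "fftshifted" wherever planes are
# indexed, i.e. DC at index floor(n/2)+1, so that plane numbering matches
# the linearly ascending partition-encoding convention.

fftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    s <- floor(n / 2)
    c(seq(s + 1, n), seq_len(s))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

ifftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    s <- ceiling(n / 2)
    c(seq(s + 1, n), seq_len(s))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# signed DFT frequencies in fftshifted order: -(n/2) ... (n/2 - 1) for even n
shifted_freqs <- function(n) seq_len(n) - (floor(n / 2) + 1)

ifft <- function(x) stats::fft(x, inverse = TRUE) / length(x)
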