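# Spectral synthesis of power-law ("1/f^beta") Gaussian noise.
#
# A signal with power spectral density S(f) ~ f^(-beta) is self-affine with
# fractal dimension D = (5 - beta) / 2 for 1 < beta < 3 (equivalently
# beta = 5 - 2 D; for fractional Brownian motion D = 2 - H and
# beta = 2 H + 1). Shaping white Gaussian noise with the amplitude response
# |A(f)| ~ f^(-beta/2) therefore yields a signal whose expected Higuchi
# fractal dimension approaches the target D. O(n log n) via the FFT.

# Symmetric length-n spectral amplitude for one channel.
#
# target_fd = NA gives a flat (white) response. The response is zero at DC
# (signals are exactly zero-mean) and above cutoff_hz when given. The
# amplitude is scaled so that filtering unit-variance white noise yields a
# unit-variance signal (Parseval), making the output scale deterministic.
spectral_amplitude <- function(n, sampling_rate, target_fd = NA,
                               cutoff_hz = NULL) {
  j <- seq_len(n) - 1L
  f <- pmin(j, n - j) * sampling_rate / n   # |frequency| of each FFT bin
  if (is.na(target_fd)) {
    a <- rep(1, n)
  } else {
    beta <- 5 - 2 * target_fd
    a <- c(0, f[-1]^(-beta / 2))
  }
  a[1] <- 0
  if (!is.null(cutoff_hz)) a[f > cutoff_hz] <- 0
  nrm <- sqrt(sum(a^2) / n)
  if (nrm == 0) stop_hfd("spectral amplitude is identically zero; ",
                         "cutoff_hz below the fundamental frequency?")
  a / nrm
}

# Filter the columns of a white-noise matrix with per-column amplitudes.
# amp: n x n_channels matrix of symmetric spectral amplitudes.
filter_white <- function(white, amp) {
  n <- nrow(white)
  spec <- mvfft(white) * amp
  Re(mvfft(spec, inverse = TRUE)) / n
}

# R's mixed-radix FFT is slow when the length has large prime factors
# (arbitrary durations make that common), so synthesis runs at the next
# 2-3-5-smooth length and the result is truncated to n. The process is
# stationary, so truncation only drops samples; columns are re-centred
# because exact zero-DC holds at the padded length, not after truncation.
smooth_length <- function(n) stats::nextn(n, c(2, 3, 5))

#' Synthesize a power-law fractal signal with a target Higuchi dimension
#'
#' Generates zero-mean Gaussian noise whose power spectrum follows
#' \eqn{S(f) \propto f^{-\beta}} with \eqn{\beta = 5 - 2 D}, so that the
#' expected Higuchi fractal dimension (long windows, suitable `k_max`)
#' approaches `target_fd`. This is the fractional-Brownian-motion relation
#' \eqn{D = 2 - H}. Deterministic for a given `seed`.
#'
#' @param n_samples number of samples, at least 64.
#' @param target_fd target fractal dimension, strictly inside (1, 2).
#' @param sampling_rate sampling rate in Hz (sets the frequency axis for
#'   `cutoff_hz`; the fractal dimension itself is scale-free).
#' @param seed integer seed.
#' @param cutoff_hz optional low-pass cut-off in Hz: spectral components
#'   above it are removed, emulating band-limited acquisition. `NULL`
#'   (default) keeps the power law up to the Nyquist frequency.
#' @return Numeric vector of length `n_samples`, zero-mean, expected unit
#'   variance.
#' @examples
#' x <- synthesize_fractal_signal(4096, 1.5, 256, seed = 7)
#' higuchi_fd(x, k_max = 50)   # close to 1.5
#' @export
synthesize_fractal_signal <- function(n_samples, target_fd, sampling_rate,
                                      seed, cutoff_hz = NULL) {
  if (!is.numeric(target_fd) || length(target_fd) != 1 ||
      target_fd <= 1 || target_fd >= 2)
    stop_hfd("invalid parameter: target_fd must lie strictly in (1, 2), got ",
             target_fd)
  if (n_samples < 64) stop_hfd("n_samples must be at least 64")
  if (sampling_rate <= 0) stop_hfd("sampling_rate must be positive")
  set.seed(as.integer(seed))
  n2 <- smooth_length(n_samples)
  white <- matrix(rnorm(n2), ncol = 1)
  amp <- spectral_amplitude(n2, sampling_rate, target_fd, cutoff_hz)
  x <- drop(filter_white(white, amp))[seq_len(n_samples)]
  x - mean(x)
}

# Multichannel synthesis for one recording: one white-noise draw per
# channel, shaped per-channel. Channels with fd = NA are pure white noise
# (auxiliary leads). A flat noise floor of relative amplitude noise_sd is
# folded into the spectral amplitude in quadrature, which is equal in law
# to adding an independent white measurement-noise signal of that relative
# amplitude (a sum of independent Gaussians is Gaussian with quadrature
# amplitude).
synth_recording_matrix <- function(n_samples, fds, sampling_rate, noise_sd,
                                   cutoff_hz, amplitude_uv) {
  n_ch <- length(fds)
  n2 <- smooth_length(n_samples)
  flat <- spectral_amplitude(n2, sampling_rate, NA, NULL)
  keys <- ifelse(is.na(fds), "aux", sprintf("%.12g", fds))
  amp <- matrix(0, n2, n_ch)
  for (key in unique(keys)) {
    cols <- which(keys == key)
    a <- if (key == "aux") flat else {
      shaped <- spectral_amplitude(n2, sampling_rate, fds[cols[1]],
                                   cutoff_hz)
      sqrt(shaped^2 + (noise_sd * flat)^2)
    }
    amp[, cols] <- a
  }
  white <- matrix(rnorm(n2 * n_ch), n2, n_ch)
  x <- filter_white(white, amp)[seq_len(n_samples), , drop = FALSE]
  sweep(x, 2, colMeans(x)) * amplitude_uv
}
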