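# Zero-phase FFT-mask filtering and band-power primitives shared by the
# synthetic EEG generator, the real-time feedback engine and the offline
# preprocessing. No IIR designs: signals here are finite recordings, so a
# frequency-domain mask gives exactly linear phase (zero) and exact stopbands.

fft_freqs <- function(n, rate) {
  k <- 0:(n - 1)
  f <- k / n * rate
  f[f > rate / 2] <- f[f > rate / 2] - rate
  abs(f)
}

#' Zero-phase frequency-mask filter
#'
#' Filters a real signal by masking its DFT: bins whose (absolute) frequency
#' lies inside the kept set pass with gain 1, all others are zeroed. Used as
#' low-pass (`keep = c(0, cutoff)`), band-pass, or band-stop
#' (`drop = rbind(c(lo, hi), ...)`). Zero-phase by construction.
#'
#' @param x numeric vector.
#' @param rate sampling rate (samples/s).
#' @param keep optional `c(lo, hi)` band to keep (inclusive).
#' @param drop optional 2-column matrix of bands to zero out.
#' @return filtered numeric vector, same length as `x`.
#' @keywords internal
fft_mask_filter <- function(x, rate, keep = NULL, drop = NULL) {
  n <- length(x)
  f <- fft_freqs(n, rate)
  mask <- rep(1, n)
  if (!is.null(keep)) mask[f < keep[1] | f > keep[2]] <- 0
  if (!is.null(drop)) {
    drop <- matrix(drop, ncol = 2)
    for (i in seq_len(nrow(drop)))
      mask[f >= drop[i, 1] & f <= drop[i, 2]] <- 0
  }
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

#' 1/f^alpha ("pink") noise
#'
#' Gaussian noise with power spectral density proportional to
#' `1 / f^exponent`, the canonical EEG background. Generated by shaping
#' white Gaussian noise in the frequency domain and rescaling to unit
#' standard deviation.
#'
#' @param n number of samples.
#' @param exponent spectral slope (1 = pink, 0 = white). Default 1.
#' @return numeric vector with SD 1.
#' @keywords internal
pink_noise <- function(n, exponent = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- fft_freqs(n, 1)
  shape <- c(0, 1 / (f[-1]^(exponent / 2)))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Band power of one analysis window
#'
#' Total one-sided periodogram power of a signal segment inside a frequency
#' band: rectangular summation of the FFT periodogram bins whose centres lie
#' in `[band[1], band[2]]`. For a unit-amplitude sinusoid at an exact bin
#' frequency inside the band this returns its signal power 0.5 (Parseval).
#'
#' @param segment numeric vector (one window, length `win_s * rate`).
#' @param rate sampling rate in samples/s.
#' @param band `c(low, high)` in Hz, inside `(0, rate/2)`.
#' @return non-negative scalar power (signal units squared).
#' @examples
#' t <- seq(0, 2, length.out = 501)[-501]
#' round(window_band_power(sin(2 * pi * 10 * t), 250, c(8, 12)), 3)
#' @export
window_band_power <- function(segment, rate, band) {
  if (band[1] <= 0 || band[2] >= rate / 2 || band[1] >= band[2])
    stop("invalid parameter: band must lie within (0, rate/2)")
  n <- length(segment)
  X <- stats::fft(segment)
  k <- 1:floor(n / 2)              # positive-frequency bins
  f <- k / n * rate
  sel <- k[f >= band[1] & f <= band[2]]
  sum(2 * Mod(X[sel + 1])^2) / n^2
}

# Anti-aliased integer-factor downsampling: zero-phase low-pass at 80% of the
# target Nyquist, then decimation.
decimate_fft <- function(x, rate, new_rate) {
  k <- rate / new_rate
  if (abs(k - round(k)) > 1e-9)
    stop("downsampling factor must be an integer")
  k <- round(k)
  if (k == 1) return(x)
  y <- fft_mask_filter(x, rate, keep = c(0, 0.8 * new_rate / 2))
  y[seq(1, length(y), by = k)]
}
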