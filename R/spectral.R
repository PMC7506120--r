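#' Power spectral density of a single channel
#'
#' One-sided Hann-tapered periodogram with the mean removed, renormalized so
#' that the trapezoidal integral over frequency equals the signal variance
#' (Parseval). A constant signal yields an all-zero PSD.
#'
#' @param x Numeric series (>= 64 samples).
#' @param fs Sampling rate in Hz.
#' @return Data frame with columns `freq` (Hz, 0..fs/2) and `power`
#'   (uV^2/Hz).
#' @export
compute_psd <- function(x, fs) {
  n <- length(x)
  if (n < 64) stop("need at least 64 samples for a PSD")
  if (fs <= 0) stop("'fs' must be positive")
  v <- stats::var(x)
  x <- x - mean(x)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))     # Hann
  X <- stats::fft(x * w)
  half <- seq_len(n %/% 2 + 1)
  p <- Mod(X[half])^2
  freq <- (half - 1) * fs / n
  if (v <= 0 || sum(p) == 0) {
    p <- rep(0, length(half))
  } else {
    p <- p * v / pracma::trapz(freq, p)   # enforce Parseval exactly
  }
  data.frame(freq = freq, power = p)
}

#' Integrated PSD energy over a frequency band
#'
#' Trapezoidal integral of a PSD over `[lo, hi]` Hz, with linear
#' interpolation at the band edges. The clinical wave-band energies (delta,
#' theta, alpha, beta, gamma) and the 0.5-25 Hz feature are all obtained
#' this way.
#'
#' @param psd Data frame from [compute_psd()].
#' @param lo,hi Band edges in Hz, `0 <= lo < hi`.
#' @return Scalar energy in uV^2 (0 for an all-zero PSD).
#' @export
band_energy <- function(psd, lo, hi) {
  if (lo >= hi) stop("configuration error: need lo < hi")
  if (lo < 0) stop("configuration error: lo must be >= 0")
  f <- psd$freq; p <- psd$power
  if (all(p == 0)) return(0)
  hi <- min(hi, max(f))
  lo <- max(lo, min(f))
  inside <- f > lo & f < hi
  fg <- c(lo, f[inside], hi)
  pg <- stats::approx(f, p, xout = fg)$y
  pracma::trapz(fg, pg)
}

#' Named clinical wave-band energies
#'
#' @param psd Data frame from [compute_psd()].
#' @param fs Sampling rate in Hz (caps the gamma band at fs/2).
#' @return Named numeric vector: delta (0.5-3 Hz), theta (4-7), alpha
#'   (8-13), beta (14-30), gamma (30-fs/2).
#' @export
clinical_bands <- function(psd, fs) {
  c(delta = band_energy(psd, 0.5, 3),
    theta = band_energy(psd, 4, 7),
    alpha = band_energy(psd, 8, 13),
    beta  = band_energy(psd, 14, 30),
    gamma = band_energy(psd, 30, fs / 2))
}

#' Per-epoch PSD feature
#'
#' The scalar spectral feature used for classification: the PSD integrated
#' over 0.5-25 Hz for each selected channel, averaged arithmetically across
#' channels. When `n_strongest` is given the epoch is first restricted to
#' its strongest channels via [select_strongest()].
#'
#' @param epoch An [eeg_epoch] (normally already filtered).
#' @param lo,hi Integration band in Hz (defaults 0.5 and 25).
#' @param n_strongest Optional channel count for strongest-channel selection;
#'   `NULL` uses all channels as given.
#' @return Scalar band energy in uV^2.
#' @export
epoch_psd_feature <- function(epoch, lo = 0.5, hi = 25, n_strongest = NULL) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (!is.null(n_strongest)) epoch <- select_strongest(epoch, n_strongest)
  e <- apply(epoch$data, 1, function(ch)
    band_energy(compute_psd(ch, epoch$fs), lo, hi))
  mean(e)
}
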