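#' Preprocessing configuration
#'
#' Settings reproducing the clinical acquisition chain: a 0.1-70 Hz analog
#' bandwidth and a 50 Hz mains notch, plus the number of strongest channels
#' retained for feature extraction.
#'
#' @param bandpass Length-2 numeric, band edges in Hz (default `c(0.1, 70)`).
#' @param notch Mains notch frequency in Hz (default 50); `NA` disables it.
#' @param n_strongest Number of strongest channels kept (default 10).
#' @return List of class `preprocess_config`.
#' @export
preprocess_config <- function(bandpass = c(0.1, 70), notch = 50,
                              n_strongest = 10) {
  if (length(bandpass) != 2 || bandpass[1] <= 0 || bandpass[1] >= bandpass[2])
    stop("configuration error: need 0 < bandpass[1] < bandpass[2]")
  if (n_strongest < 1)
    stop("configuration error: n_strongest must be >= 1")
  structure(list(bandpass = as.numeric(bandpass), notch = notch,
                 n_strongest = as.integer(n_strongest)),
            class = "preprocess_config")
}

#' Band-limit and notch-filter an epoch
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass over
#' `cfg$bandpass` and a narrow zero-phase band-stop (Q ~ 30) at `cfg$notch`,
#' channel by channel, after removing each channel's mean. This reproduces
#' digitally the analog 0.1-70 Hz bandwidth and 50 Hz notch of the clinical
#' recordings so that synthetic data pass through the same chain.
#'
#' @param epoch An [eeg_epoch].
#' @param cfg A [preprocess_config].
#' @return The filtered epoch (same shape, DC removed).
#' @export
filter_epoch <- function(epoch, cfg = preprocess_config()) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  fs <- epoch$fs
  hi <- cfg$bandpass[2]
  if (fs <= 2 * hi)
    stop("configuration error: bandpass upper edge must be below fs/2")
  nyq <- fs / 2
  n <- ncol(epoch$data)
  bp <- signal::butter(4, cfg$bandpass / nyq, type = "pass")
  f <- dft_freqs(n, fs)
  H <- butter_mag(bp, f, fs)^2           # forward-backward = |H|^2, order 4
  use_notch <- !is.null(cfg$notch) && !is.na(cfg$notch) && cfg$notch < nyq
  if (use_notch) {
    bw <- cfg$notch / 30                 # Q ~ 30
    ns <- signal::butter(2, c(cfg$notch - bw / 2, cfg$notch + bw / 2) / nyq,
                         type = "stop")
    H <- H * butter_mag(ns, f, fs)^2
  }
  out <- epoch$data
  for (k in seq_len(nrow(out))) {
    x <- out[k, ] - mean(out[k, ])
    out[k, ] <- Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
  }
  epoch$data <- out
  epoch
}

# two-sided DFT bin frequencies folded to [0, fs/2]
dft_freqs <- function(n, fs) {
  k <- seq_len(n) - 1
  pmin(k, n - k) * fs / n
}

# magnitude response of an IIR filter at physical frequencies f.
# Zero-phase filtering of a fixed-length epoch is applied in the frequency
# domain (epoch spectrum times |H|^2): on finite epochs this is free of the
# edge transients that time-domain forward-backward filtering leaves.
butter_mag <- function(flt, f, fs) {
  u <- exp(-2i * pi * f / fs)            # z^-1 on the unit circle
  horner <- function(coef) Reduce(function(acc, ck) acc * u + ck,
                                  rev(coef), init = 0 + 0i)
  Mod(horner(flt$b) / horner(flt$a))
}

#' Keep the strongest channels of an epoch
#'
#' Ranks channels by per-channel variance of the (already filtered) epoch,
#' descending, and keeps the top `k` -- the "10 strongest signals from 19
#' electrodes" selection. Ties are broken deterministically by channel-name
#' order.
#'
#' @param epoch An [eeg_epoch].
#' @param k Number of channels to keep; must not exceed the channel count.
#' @return The epoch restricted to the `k` strongest channels, in rank order.
#' @export
select_strongest <- function(epoch, k = 10) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (k > nrow(epoch$data))
    stop("configuration error: k exceeds the number of channels")
  v <- apply(epoch$data, 1, stats::var)
  ord <- order(-v, epoch$channel_names)[seq_len(k)]
  epoch$data <- epoch$data[ord, , drop = FALSE]
  epoch$channel_names <- epoch$channel_names[ord]
  epoch
}
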