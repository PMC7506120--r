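# Seeded synthetic EEG: colored-noise background with an alpha rhythm, plus
# the seven classical epileptiform waveform classes with clinically defined
# durations and amplitudes. Stands in for undeposited clinical recordings;
# all randomness flows from an explicit seed.

#' Epileptiform discharge subtypes
#'
#' The seven discharge classes the generator can produce, with their
#' default mix (the clinical case counts: 69 spikes, 82 sharp waves, 174
#' spike-and-slow-wave, 72 sharp-and-slow-wave, 64 polyspike, 77
#' polyspike-and-slow-wave, 2 spike-rhythm; total 540).
#'
#' @format Named integer vector.
#' @export
discharge_subtypes <- c(spike = 69L, sharp = 82L, spike_slow = 174L,
                        sharp_slow = 72L, polyspike = 64L,
                        polyspike_slow = 77L, spike_rhythm = 2L)

#' Synthetic-EEG generator configuration
#'
#' @param fs Sampling rate in Hz (default 256).
#' @param epoch_seconds Epoch length in seconds (default 4).
#' @param n_channels Channel count (default 19, the 10-20 montage).
#' @param channel_names Channel labels.
#' @param bg_slope Spectral slope alpha of the 1/f^alpha background noise
#'   (default 1).
#' @param bg_shared_sd,bg_channel_sd SD (uV) of the shared and
#'   channel-specific background noise components (defaults 20 and 12;
#'   together with the alpha rhythm this gives a 25-35 uV RMS background,
#'   typical of scalp EEG).
#' @param alpha_freq,alpha_amp Alpha-rhythm frequency (Hz) and amplitude
#'   range (uV) (defaults 10 Hz, 5-15 uV).
#' @param n_inject_channels Range of channels a discharge is injected on
#'   (default 10-19, so strongest-channel selection predominantly captures
#'   discharge-bearing channels).
#' @param n_events Range of discharge events per epileptiform epoch for the
#'   transient subtypes (default 6-12, a run of interictal discharges at
#'   the typical 1.5-3/s repetition within the 4 s epoch).
#' @return List of class `generator_config`.
#' @export
generator_config <- function(fs = 256, epoch_seconds = 4, n_channels = 19,
                             channel_names = channels_1020,
                             bg_slope = 1, bg_shared_sd = 20,
                             bg_channel_sd = 12, alpha_freq = 10,
                             alpha_amp = c(5, 15),
                             n_inject_channels = c(10, 19),
                             n_events = c(6, 12)) {
  if (length(channel_names) < n_channels)
    channel_names <- paste0("ch", seq_len(n_channels))
  structure(list(fs = fs, epoch_seconds = epoch_seconds,
                 n_channels = n_channels,
                 channel_names = channel_names[seq_len(n_channels)],
                 bg_slope = bg_slope, bg_shared_sd = bg_shared_sd,
                 bg_channel_sd = bg_channel_sd, alpha_freq = alpha_freq,
                 alpha_amp = alpha_amp,
                 n_inject_channels = n_inject_channels,
                 n_events = n_events),
            class = "generator_config")
}

# 1/f^alpha noise of unit variance via spectral shaping of white noise
colored_noise <- function(n, alpha) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w)
  X <- stats::fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k)
  f[1] <- 1                                      # avoid f = 0
  X <- X * f^(-alpha / 2)
  X[1] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  as.vector(scale(x))
}

#' Generate a normal background EEG epoch
#'
#' Each channel mixes a shared 1/f^alpha source (common cortical
#' background), a channel-specific 1/f^alpha component, and a 10 Hz alpha
#' rhythm with a common random phase and channel-varying gain. Amplitudes
#' are in the tens of microvolts.
#'
#' @param cfg A [generator_config].
#' @param seed Integer seed; same seed, same epoch.
#' @return An [eeg_epoch] with `label = "normal"`.
#' @export
gen_background <- function(cfg = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(round(cfg$fs * cfg$epoch_seconds))
  nch <- cfg$n_channels
  shared <- colored_noise(n, cfg$bg_slope) * cfg$bg_shared_sd
  phase <- stats::runif(1, 0, 2 * pi)
  amp <- stats::runif(1, cfg$alpha_amp[1], cfg$alpha_amp[2])
  tt <- seq_len(n) / cfg$fs
  alpha_wave <- sin(2 * pi * cfg$alpha_freq * tt + phase)
  data <- matrix(0, nch, n)
  for (k in seq_len(nch)) {
    g_sh <- stats::runif(1, 0.7, 1)
    g_al <- stats::runif(1, 0.5, 1)
    data[k, ] <- g_sh * shared +
      colored_noise(n, cfg$bg_slope) * cfg$bg_channel_sd +
      g_al * amp * alpha_wave
  }
  eeg_epoch(data, cfg$fs, channel_names = cfg$channel_names,
            label = "normal")
}

# biphasic transient: difference of two Gaussian lobes spanning exactly
# `dur_s` seconds, peak absolute amplitude `amp` uV, negative main phase
# (surface-negative spikes are the clinical convention)
biphasic <- function(dur_s, amp, fs) {
  n <- max(3L, as.integer(round(dur_s * fs)))
  u <- seq(0, 1, length.out = n)
  w <- exp(-((u - 0.35) / 0.13)^2) - 0.55 * exp(-((u - 0.7) / 0.22)^2)
  -amp * w / max(abs(w))
}

half_sine <- function(dur_s, amp, fs) {
  n <- max(3L, as.integer(round(dur_s * fs)))
  amp * sin(pi * seq(0, 1, length.out = n))
}

runif1 <- function(lim) stats::runif(1, lim[1], lim[2])

#' Generate one epileptiform discharge waveform
#'
#' Parametric templates following the clinical definitions: spikes are
#' 20-70 ms biphasic transients above 50 uV; sharp waves are 70-200 ms at
#' 100-200 uV; the *-and-slow-wave complexes append a half-sine slow wave
#' of higher amplitude than the transient; polyspikes concatenate two or
#' more spikes; the spike rhythm is a 10-25 Hz spike train at 100-200 uV
#' lasting more than 1 s.
#'
#' @param subtype One of `names(discharge_subtypes)`.
#' @param cfg A [generator_config].
#' @param seed Optional integer seed.
#' @return Numeric waveform (uV) at `cfg$fs`, with attributes
#'   `duration_s` and `amplitude` recording the drawn parameters of the
#'   primary transient.
#' @export
gen_discharge <- function(subtype, cfg = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- cfg$fs
  spike1 <- function() {
    # duration from the clinical definition; amplitudes of clearly marked
    # scalp spikes run well above the 50 uV floor
    d <- stats::runif(1, 0.020, 0.070); a <- stats::runif(1, 100, 300)
    list(w = biphasic(d, a, fs), d = d, a = a)
  }
  sharp1 <- function() {
    d <- stats::runif(1, 0.070, 0.200); a <- stats::runif(1, 100, 200)
    list(w = biphasic(d, a, fs), d = d, a = a)
  }
  slow_after <- function(a_transient) {
    half_sine(stats::runif(1, 0.150, 0.350),
              a_transient * stats::runif(1, 1.2, 1.8), fs)
  }
  out <- switch(subtype,
    spike = {
      s <- spike1()
      structure(s$w, duration_s = s$d, amplitude = s$a)
    },
    sharp = {
      s <- sharp1()
      structure(s$w, duration_s = s$d, amplitude = s$a)
    },
    spike_slow = {
      s <- spike1()
      structure(c(s$w, slow_after(s$a)), duration_s = s$d, amplitude = s$a)
    },
    sharp_slow = {
      s <- sharp1()
      structure(c(s$w, slow_after(s$a)), duration_s = s$d, amplitude = s$a)
    },
    polyspike = {
      k <- sample(2:5, 1)
      ss <- replicate(k, spike1(), simplify = FALSE)
      structure(unlist(lapply(ss, `[[`, "w")),
                duration_s = ss[[1]]$d, amplitude = ss[[1]]$a)
    },
    polyspike_slow = {
      k <- sample(2:5, 1)
      ss <- replicate(k, spike1(), simplify = FALSE)
      a_max <- max(vapply(ss, `[[`, 0, "a"))
      structure(c(unlist(lapply(ss, `[[`, "w")), slow_after(a_max)),
                duration_s = ss[[1]]$d, amplitude = ss[[1]]$a)
    },
    spike_rhythm = {
      f <- stats::runif(1, 10, 25)
      a <- stats::runif(1, 100, 200)
      dur <- stats::runif(1, 1.5, 3)
      cyc <- biphasic(1 / f, a, fs)
      n_cyc <- ceiling(dur * f)
      w <- rep(cyc, length.out = max(ceiling(dur * fs), length(cyc)))
      structure(w, duration_s = length(w) / fs, amplitude = a)
    },
    stop("configuration error: unknown discharge subtype '", subtype, "'")
  )
  out
}

#' Generate a labelled synthetic EEG dataset
#'
#' Normal epochs are pure background; epileptiform epochs are background
#' plus discharge waveforms injected on a random subset of at least 10
#' channels, at random onsets, with channel-varying gain. Transient
#' subtypes are injected as a run of several events per epoch; the spike
#' rhythm as a single long train. Class sizes and the subtype mix default
#' to the clinical composition (100 normal / 540 epileptiform).
#'
#' @param n_normal,n_epileptiform Class sizes (defaults 100 and 540).
#' @param subtype_mix Named vector of subtype proportions or counts;
#'   default [discharge_subtypes].
#' @param cfg A [generator_config].
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param out_dir Optional directory: epochs are written as EDF files with
#'   a `manifest.csv` (epoch_id, source file, offset, label, subtype).
#' @return List with `epochs` (list of [eeg_epoch]) and `manifest`
#'   (data frame).
#' @export
gen_dataset <- function(n_normal = 100, n_epileptiform = 540,
                        subtype_mix = discharge_subtypes,
                        cfg = generator_config(), seed = 1,
                        out_dir = NULL) {
  set.seed(seed)
  n_samp <- as.integer(round(cfg$fs * cfg$epoch_seconds))
  subtypes <- rep(names(subtype_mix),
                  round_counts(subtype_mix, n_epileptiform))
  epochs <- vector("list", n_normal + n_epileptiform)
  man <- vector("list", n_normal + n_epileptiform)
  idx <- 0L
  for (k in seq_len(n_normal)) {
    idx <- idx + 1L
    ep <- gen_background(cfg)
    ep$epoch_id <- sprintf("normal-%04d", k)
    epochs[[idx]] <- ep
    man[[idx]] <- data.frame(epoch_id = ep$epoch_id, source_file = NA,
                             offset = 0L, label = "normal", subtype = NA)
  }
  for (k in seq_len(n_epileptiform)) {
    idx <- idx + 1L
    st <- subtypes[k]
    ep <- gen_background(cfg)
    ep$label <- "epileptiform"
    ep$subtype <- st
    ep$epoch_id <- sprintf("epi-%04d", k)
    n_events <- if (st == "spike_rhythm") 1L
                else sample(cfg$n_events[1]:cfg$n_events[2], 1)
    n_ch <- sample(cfg$n_inject_channels[1]:cfg$n_inject_channels[2], 1)
    chans <- sample(cfg$n_channels, n_ch)
    gains <- stats::runif(n_ch, 0.6, 1)
    # partition the epoch so events do not overlap
    bounds <- floor(seq(1, n_samp + 1, length.out = n_events + 1))
    for (ev in seq_len(n_events)) {
      w <- gen_discharge(st, cfg)
      avail <- bounds[ev + 1] - bounds[ev] - length(w)
      onset <- bounds[ev] + if (avail > 0) sample(avail, 1) else 0L
      span <- onset:min(onset + length(w) - 1L, n_samp)
      ep$data[chans, span] <- ep$data[chans, span] +
        outer(gains, w[seq_along(span)])
    }
    epochs[[idx]] <- ep
    man[[idx]] <- data.frame(epoch_id = ep$epoch_id, source_file = NA,
                             offset = 0L, label = "epileptiform",
                             subtype = st)
  }
  manifest <- do.call(rbind, man)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest$source_file <- paste0(manifest$epoch_id, ".edf")
    for (i in seq_along(epochs))
      write_edf(epochs[[i]], file.path(out_dir, manifest$source_file[i]))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(epochs = epochs, manifest = manifest)
}

# allocate n slots proportionally to `mix`, largest-remainder rounding
round_counts <- function(mix, n) {
  p <- mix / sum(mix)
  cnt <- floor(p * n)
  rem <- n - sum(cnt)
  if (rem > 0) {
    o <- order(p * n - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1L
  }
  as.integer(cnt)
}
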