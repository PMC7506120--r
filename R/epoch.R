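#' Standard 10-20 scalp electrode labels
#'
#' The 19 electrode names of the international 10-20 system in the
#' conventional acquisition order, used as default channel names throughout
#' the package.
#'
#' @format Character vector of length 19.
#' @export
channels_1020 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                   "T3", "C3", "Cz", "C4", "T4",
                   "T5", "P3", "Pz", "P4", "T6", "O1", "O2")

#' Construct an EEG epoch
#'
#' An `eeg_epoch` is one fixed-length multi-channel EEG segment in microvolts
#' with its sampling rate, channel names, and an optional class label. The
#' default configuration mirrors clinical scalp EEG: 19 channels of the 10-20
#' system, 256 Hz, 4 s (1024 samples).
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector, one name per row of `data`.
#' @param label Optional class label, `"normal"` or `"epileptiform"`.
#' @param subtype Optional character vector of epileptiform discharge
#'   subtype(s) (an epoch may carry more than one).
#' @param epoch_id Opaque identifier; generated if missing.
#' @return Object of class `eeg_epoch`: a list with elements `data`, `fs`,
#'   `channel_names`, `label`, `subtype`, `epoch_id`.
#' @export
eeg_epoch <- function(data, fs, channel_names = rownames(data),
                      label = NULL, subtype = NULL, epoch_id = NULL) {
  data <- as.matrix(data)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("'channel_names' must have one entry per row of 'data'")
  if (!all(is.finite(data)))
    stop("epoch data must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a positive scalar")
  if (!is.null(label))
    label <- match.arg(label, c("normal", "epileptiform"))
  if (is.null(epoch_id))
    epoch_id <- next_epoch_id()
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         label = label, subtype = subtype, epoch_id = epoch_id),
    class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch %s> %d channels x %d samples @ %g Hz (%.3g s)\n",
              x$epoch_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  if (!is.null(x$label))
    cat("  label:", x$label,
        if (!is.null(x$subtype)) paste0("(", paste(x$subtype, collapse = "+"), ")"),
        "\n")
  rms <- sqrt(mean(x$data^2))
  cat(sprintf("  RMS %.1f uV, range [%.1f, %.1f] uV\n",
              rms, min(x$data), max(x$data)))
  invisible(x)
}

#' Segment a continuous recording into fixed-length epochs
#'
#' Cuts a multi-channel recording into consecutive non-overlapping epochs of
#' `epoch_seconds` each (half-open sample windows); a trailing partial window
#' is discarded. Matches the clinical protocol of segmenting recordings into
#' 4 s epochs.
#'
#' @param signals Channels x samples numeric matrix, or the list returned by
#'   [read_edf()].
#' @param fs Sampling rate in Hz (taken from `signals` when it is a
#'   recording list).
#' @param epoch_seconds Epoch duration in seconds; `epoch_seconds * fs` must
#'   be a positive integer.
#' @param channel_names Optional channel names.
#' @param label,subtype Optional label/subtype applied to every epoch.
#' @param id_prefix Prefix for the generated epoch ids.
#' @return List of [eeg_epoch] objects, possibly empty (with a warning) when
#'   the recording is shorter than one epoch.
#' @export
segment_epochs <- function(signals, fs = NULL, epoch_seconds = 4,
                           channel_names = NULL, label = NULL,
                           subtype = NULL, id_prefix = "epoch") {
  if (is.list(signals) && !is.null(signals$signals)) {
    if (is.null(fs)) fs <- signals$fs
    if (is.null(channel_names)) channel_names <- signals$channel_names
    signals <- signals$signals
  }
  signals <- as.matrix(signals)
  if (is.null(fs)) stop("'fs' is required")
  n_ep_samples <- epoch_seconds * fs
  if (abs(n_ep_samples - round(n_ep_samples)) > 1e-9 || n_ep_samples < 1)
    stop("'epoch_seconds' * 'fs' must be a positive integer")
  n_ep_samples <- as.integer(round(n_ep_samples))
  total <- ncol(signals)
  n_epochs <- total %/% n_ep_samples
  if (n_epochs == 0L) {
    warning("recording shorter than one epoch; returning empty list")
    return(list())
  }
  lapply(seq_len(n_epochs), function(k) {
    idx <- ((k - 1L) * n_ep_samples + 1L):(k * n_ep_samples)
    eeg_epoch(signals[, idx, drop = FALSE], fs,
              channel_names = channel_names, label = label,
              subtype = subtype,
              epoch_id = sprintf("%s-%04d", id_prefix, k))
  })
}

# package-local counter so auto-generated epoch ids never touch the RNG stream
.sdleeg_state <- new.env(parent = emptyenv())
.sdleeg_state$epoch_counter <- 0L

next_epoch_id <- function() {
  .sdleeg_state$epoch_counter <- .sdleeg_state$epoch_counter + 1L
  sprintf("epoch-%06d", .sdleeg_state$epoch_counter)
}
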