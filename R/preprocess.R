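# Preprocessing: band-pass filtering, average reference, epoching with
# amplitude-based rejection.

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass (default 2-20 Hz) forward and
#' backward (`signal::filtfilt`), giving zero phase distortion — topography
#' timing is untouched, which matters for microstate boundaries. The
#' per-channel mean is removed before filtering, so DC is nulled exactly.
#'
#' @param rec An [eeg_recording()].
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Butterworth order (default 4).
#' @return A filtered copy of the recording.
#' @export
bandpass_filter <- function(rec, low = 2, high = 20, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq)) {
    stopf("band [%g, %g] Hz must lie strictly inside (0, %g) Hz", low, high, nyq)
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  centered <- rec$data - rowMeans(rec$data)
  filtered <- t(apply(centered, 1L, function(x) signal::filtfilt(bf, x)))
  eeg_recording(filtered, rec$sampling_rate, rec$channel_labels, rec$reference)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every sample, so the
#' spatial mean is zero at all times. Idempotent; leaves the GFP unchanged
#' (GFP is computed about the spatial mean).
#'
#' @param rec An [eeg_recording()].
#' @return The average-referenced recording.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  data <- sweep(rec$data, 2L, colMeans(rec$data), "-")
  eeg_recording(data, rec$sampling_rate, rec$channel_labels, reference = "average")
}

#' Cut a recording into fixed-length epochs and reject by amplitude
#'
#' The recording is segmented into consecutive, non-overlapping epochs starting
#' at the first sample (a trailing partial epoch is discarded). Any epoch
#' containing a sample whose absolute amplitude exceeds `threshold_uV` is
#' dropped; kept epochs are reported by their original (1-based) indices.
#'
#' @param rec An [eeg_recording()].
#' @param epoch_ms Epoch length in ms; `epoch_ms * fs / 1000` must be an
#'   integer >= 2.
#' @param threshold_uV Absolute-amplitude rejection threshold in microvolts
#'   (default 80); `Inf` keeps everything.
#' @return An object of class `eeg_epochs` with fields `data` (epochs x
#'   channels x samples array), `epoch_ms`, `kept_epoch_indices`,
#'   `rejection_threshold`, `sampling_rate`, `channel_labels`.
#' @export
epoch_and_reject <- function(rec, epoch_ms = 2000, threshold_uV = 80) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_per <- epoch_ms * rec$sampling_rate / 1000
  if (abs(n_per - round(n_per)) > 1e-9 || round(n_per) < 2) {
    stopf("epoch_ms x sampling_rate / 1000 must be an integer >= 2")
  }
  n_per <- as.integer(round(n_per))
  n_total <- ncol(rec$data)
  n_epochs <- n_total %/% n_per
  if (n_epochs < 1L) stopf("recording (%d samples) shorter than one epoch (%d samples)",
                           n_total, n_per)
  arr <- array(rec$data[, seq_len(n_epochs * n_per)],
               dim = c(nrow(rec$data), n_per, n_epochs))
  keep <- vapply(seq_len(n_epochs),
                 function(e) max(abs(arr[, , e])) <= threshold_uV, logical(1))
  if (!any(keep)) stopf("all %d epochs exceed the %g uV rejection threshold",
                        n_epochs, threshold_uV)
  arr <- arr[, , keep, drop = FALSE]
  structure(
    list(data = aperm(arr, c(3L, 1L, 2L)), epoch_ms = epoch_ms,
         kept_epoch_indices = which(keep), rejection_threshold = threshold_uV,
         sampling_rate = rec$sampling_rate, channel_labels = rec$channel_labels),
    class = "eeg_epochs"
  )
}

#' Concatenate kept epochs back into a continuous recording
#'
#' Reproduces the retained portion of the source recording exactly (in kept
#' order). Mainly used to verify the epoching round trip and to backfit a
#' recording as a single stretch.
#'
#' @param epochs An `eeg_epochs` object.
#' @return An [eeg_recording()].
#' @export
epochs_to_recording <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  d <- dim(epochs$data)
  mat <- matrix(aperm(epochs$data, c(2L, 3L, 1L)), nrow = d[2])
  eeg_recording(mat, epochs$sampling_rate, epochs$channel_labels, "average")
}

#' Treat a whole recording as a single epoch
#'
#' Convenience for backfitting a continuous recording without epoch
#' boundaries (e.g. to compare against a simulator's run list).
#'
#' @param rec An [eeg_recording()].
#' @return An `eeg_epochs` with one epoch spanning the recording.
#' @export
as_single_epoch <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  epoch_and_reject(rec, epoch_ms = ncol(rec$data) / rec$sampling_rate * 1000,
                   threshold_uV = Inf)
}
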