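#' Construct a continuous EEG recording
#'
#' A recording is a channels x samples matrix of scalp potentials in microvolts
#' together with channel labels, the sampling rate and the current reference.
#'
#' @param data Numeric matrix, channels x samples, in microvolts. All values
#'   must be finite.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character vector of channel names; defaults to
#'   `"ch01"`, `"ch02"`, ...
#' @param reference Reference description, e.g. a channel label or `"average"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channel_labels = NULL,
                          reference = "unknown") {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stopf("a recording needs at least 2 channels")
  if (!all(is.finite(data))) stopf("recording contains non-finite samples")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0) {
    stopf("sampling_rate must be a single positive number")
  }
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stopf("channel_labels length (%d) != number of channels (%d)",
          length(channel_labels), nrow(data))
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, channel_labels = channel_labels,
         sampling_rate = sampling_rate, reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate, x$reference))
  invisible(x)
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples @ %g Hz (epoch %g ms, threshold %g uV)\n",
              length(x$kept_epoch_indices), dim(x$data)[1], dim(x$data)[2],
              x$sampling_rate, x$epoch_ms, x$rejection_threshold))
  invisible(x)
}

#' Write / read a recording as plain-text CSV
#'
#' One row per channel, one column per sample, with channel labels in the first
#' column. Intended for small recordings and interchange with external tools;
#' metadata (sampling rate, reference) is stored in a JSON sidecar
#' `<path>.meta.json`.
#'
#' @param rec An `eeg_recording`.
#' @param path Output CSV path.
#' @return `write_recording_csv` returns `path` invisibly; `read_recording_csv`
#'   returns an `eeg_recording`.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- data.frame(channel = rec$channel_labels, rec$data, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(sampling_rate = rec$sampling_rate, reference = rec$reference),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  eeg_recording(as.matrix(df[, -1, drop = FALSE]),
                sampling_rate = meta$sampling_rate,
                channel_labels = df[[1]],
                reference = meta$reference)
}

#' Write / read a behavioral cohort table
#'
#' The behavioral table has one row per subject with columns `subject_id`,
#' `wcts_total`, the four trait-creativity subscales (`risk_taking`,
#' `curiosity`, `imagination`, `challenge`), `rses_total`, `sex` (0/1) and
#' `age` (years).
#'
#' @param behavior A data frame/tibble with the columns above.
#' @param path CSV path.
#' @export
write_behavior_table <- function(behavior, path) {
  utils::write.csv(as.data.frame(behavior), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_table
#' @export
read_behavior_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' Persist a template set as JSON
#'
#' Stores channel labels, the K template maps, and fit diagnostics so templates
#' can be re-used across runs or inspected externally.
#'
#' @param ts A `template_set`.
#' @param path Output JSON path.
#' @param channel_labels Optional channel labels stored alongside the maps.
#' @export
write_templates_json <- function(ts, path, channel_labels = NULL) {
  stopifnot(inherits(ts, "template_set"))
  if (is.null(channel_labels)) channel_labels <- sprintf("ch%02d", seq_len(nrow(ts$maps)))
  jsonlite::write_json(
    list(k = ts$k, gev = ts$gev, cv_value = ts$cv_value, source = ts$source,
         state_names = colnames(ts$maps), channel_labels = channel_labels,
         maps = unname(apply(ts$maps, 2L, identity, simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_templates_json
#' @export
read_templates_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  maps <- if (is.list(obj$maps)) {
    do.call(cbind, lapply(obj$maps, unlist))
  } else {
    t(as.matrix(obj$maps))  # simplification yields one row per map
  }
  if (!is.null(obj$state_names) && length(obj$state_names) == ncol(maps)) {
    colnames(maps) <- obj$state_names
  }
  new_template_set(maps, gev = obj$gev, cv_value = obj$cv_value, source = obj$source)
}
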