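#' Construct an EEG recording object
#'
#' A recording holds a channels x samples potential matrix in microvolts plus
#' the montage labels, sampling rate, and subject/condition/group metadata.
#'
#' @param data Numeric matrix, channels x samples (uV).
#' @param channels Character vector of channel labels, one per row of `data`.
#' @param rate_hz Sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @param condition `"rest"` or `"task"`.
#' @param group `"good"` or `"poor"`.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, channels, rate_hz,
                          subject_id = NA_character_,
                          condition = NA_character_,
                          group = NA_character_) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("recording data must be finite", call. = FALSE)
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be > 0", call. = FALSE)
  if (length(channels) != nrow(data)) {
    stop("length(channels) must equal nrow(data)", call. = FALSE)
  }
  dimnames(data) <- list(channels, NULL)
  structure(
    list(data = data, channels = as.character(channels), rate_hz = rate_hz,
         subject_id = subject_id, condition = condition, group = group),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate_hz, ncol(x$data) / x$rate_hz))
  cat(sprintf("  subject: %s  condition: %s  group: %s\n",
              x$subject_id, x$condition, x$group))
  invisible(x)
}

new_epoch <- function(data, rate_hz, subject_id, condition, group, epoch_index) {
  structure(
    list(data = data, rate_hz = rate_hz, subject_id = subject_id,
         condition = condition, group = group, epoch_index = epoch_index,
         rejected = FALSE, reject_reason = NA_character_),
    class = "eeg_epoch"
  )
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> #%d %d ch x %d samples @ %g Hz%s\n",
              x$epoch_index, nrow(x$data), ncol(x$data), x$rate_hz,
              if (isTRUE(x$rejected)) paste0(" [rejected: ", x$reject_reason, "]") else ""))
  invisible(x)
}

#' Construct a microstate label sequence
#'
#' Per-sample class labels (integers 1..k mapping onto archetypes A-D) for one
#' epoch or continuous stretch, optionally with the per-sample absolute spatial
#' correlation to the assigned map.
#'
#' @param labels Integer vector of class indices in 1..k.
#' @param rate_hz Sampling rate in Hz.
#' @param classes Character vector of class names (default A-D).
#' @param corr Optional numeric vector of |spatial correlation| per sample.
#' @return An object of class `ms_labels`.
#' @export
new_labels <- function(labels, rate_hz, classes = MS_CLASSES, corr = NULL) {
  labels <- as.integer(labels)
  stopifnot(length(labels) >= 1L, all(labels >= 1L), all(labels <= length(classes)))
  structure(
    list(labels = labels, rate_hz = rate_hz, classes = classes, corr = corr),
    class = "ms_labels"
  )
}

#' @export
print.ms_labels <- function(x, ...) {
  cat(sprintf("<ms_labels> %d samples @ %g Hz, classes %s\n",
              length(x$labels), x$rate_hz, paste(x$classes, collapse = "")))
  invisible(x)
}
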