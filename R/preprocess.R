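CANONICAL_CHANNELS <- c("Fp1", "Fp2", "F3", "F4", "Fz", "F7", "F8",
                        "C3", "C4", "Cz", "P3", "P4", "Pz", "O1", "O2",
                        "T3", "T4", "T5", "T6")

#' Write a recording as a portable matrix + JSON sidecar
#'
#' The data matrix goes to `<path>.tsv` (samples in rows, one column per
#' channel, header = channel labels); metadata (channel order, rate, subject,
#' condition, group) to `<path>.json`.
#'
#' @param rec An `eeg_recording`.
#' @param path File path prefix (no extension).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  dt <- data.table::as.data.table(t(rec$data))
  data.table::setnames(dt, rec$channels)
  data.table::fwrite(dt, paste0(path, ".tsv"), sep = "\t")
  meta <- list(channels = rec$channels, rate_hz = rec$rate_hz,
               subject_id = rec$subject_id, condition = rec$condition,
               group = rec$group, units = "uV")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a recording from a matrix + JSON sidecar
#'
#' Channels are reordered into the canonical 19-channel 10-20 montage order
#' when all 19 names are present; a missing or unknown montage channel is an
#' error unless `require_montage = FALSE`.
#'
#' @param path File path prefix used by [write_recording()].
#' @param require_montage Enforce the 19-channel 10-20 montage (default TRUE).
#' @return An `eeg_recording` in canonical channel order.
#' @export
load_recording <- function(path, require_montage = TRUE) {
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  if (!file.exists(tsv) || !file.exists(json)) {
    stop("io-error: missing ", tsv, " or ", json, call. = FALSE)
  }
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  dt <- data.table::fread(tsv, sep = "\t")
  mat <- t(as.matrix(dt))
  channels <- colnames(dt)
  if (require_montage) {
    missing <- setdiff(CANONICAL_CHANNELS, channels)
    extra <- setdiff(channels, CANONICAL_CHANNELS)
    if (length(missing) || length(extra)) {
      stop("channel-mismatch: missing [", paste(missing, collapse = ","),
           "] unknown [", paste(extra, collapse = ","), "]", call. = FALSE)
    }
    mat <- mat[match(CANONICAL_CHANNELS, channels), , drop = FALSE]
    channels <- CANONICAL_CHANNELS
  }
  new_recording(mat, channels, meta$rate_hz,
                subject_id = meta$subject_id %||% NA_character_,
                condition = meta$condition %||% NA_character_,
                group = meta$group %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward-backward
#' (`signal::filtfilt`) per channel, so the pass band (default 2-20 Hz, the
#' band used for archetype microstate derivation) is preserved with zero phase
#' distortion.
#'
#' @param rec An `eeg_recording`.
#' @param low_hz,high_hz Band edges in Hz (defaults 2 and 20).
#' @param order Butterworth order per edge (default 4).
#' @return Filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low_hz = 2, high_hz = 20, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$rate_hz / 2
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyq)) {
    stop("invalid band: need 0 < low < high < rate/2", call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- rec
  out$data <- t(apply(rec$data, 1L, function(ch) signal::filtfilt(bf, ch)))
  rownames(out$data) <- rec$channels
  out
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every sample, so
#' channel means per sample are 0 (+- 1e-9 uV).
#'
#' @param rec An `eeg_recording` with >= 2 channels.
#' @return Re-referenced `eeg_recording`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$data) < 2L) stop("need >= 2 channels to average-reference", call. = FALSE)
  out <- rec
  out$data <- demean_channels(rec$data)
  out
}

#' Cut a recording into consecutive fixed-length epochs
#'
#' Non-overlapping half-open windows of `length_s` seconds; a trailing
#' remainder shorter than one epoch is discarded.
#'
#' @param rec An `eeg_recording`.
#' @param length_s Epoch length in seconds (default 2).
#' @return List of `eeg_epoch` (possibly empty, with a warning).
#' @export
segment_epochs <- function(rec, length_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(length_s * rec$rate_hz)
  n_ep <- floor(ncol(rec$data) / len)
  if (n_ep == 0L) {
    warning("recording shorter than one epoch; returning empty list")
    return(list())
  }
  lapply(seq_len(n_ep), function(i) {
    idx <- ((i - 1L) * len + 1L):(i * len)
    new_epoch(rec$data[, idx, drop = FALSE], rec$rate_hz,
              rec$subject_id, rec$condition, rec$group, i)
  })
}

#' Threshold-based artifact rejection
#'
#' An epoch is rejected iff any channel's maximum absolute value exceeds
#' `amp_threshold_uv`, or any channel's variance exceeds `var_threshold`
#' (uV^2, per channel per epoch), or it appears in `manual_exclusions`
#' (a data.frame with `subject_id` and `epoch_index`, standing in for visual
#' inspection). Deterministic: the same epochs and thresholds always yield the
#' same kept set.
#'
#' @param epochs List of `eeg_epoch`.
#' @param amp_threshold_uv Amplitude criterion in uV (default 100).
#' @param var_threshold Variance criterion in uV^2 (default 500).
#' @param manual_exclusions Optional data.frame (`subject_id`, `epoch_index`).
#' @return List with `kept` (epochs) and `log` (data.frame of rejections:
#'   subject, condition, epoch_index, reason, channel, value).
#' @export
reject_artifacts <- function(epochs, amp_threshold_uv = 100, var_threshold = 500,
                             manual_exclusions = NULL) {
  log <- list()
  kept <- list()
  for (ep in epochs) {
    amps <- apply(abs(ep$data), 1L, max)
    vars <- apply(ep$data, 1L, stats::var)
    reason <- NULL
    channel <- NA_character_
    value <- NA_real_
    if (!is.null(manual_exclusions) &&
        any(manual_exclusions$subject_id == ep$subject_id &
            manual_exclusions$epoch_index == ep$epoch_index)) {
      reason <- "manual"
    } else if (any(amps > amp_threshold_uv)) {
      j <- which.max(amps)
      reason <- "amplitude"; channel <- rownames(ep$data)[j]; value <- amps[j]
    } else if (any(vars > var_threshold)) {
      j <- which.max(vars)
      reason <- "variance"; channel <- rownames(ep$data)[j]; value <- vars[j]
    }
    if (is.null(reason)) {
      kept[[length(kept) + 1L]] <- ep
    } else {
      ep$rejected <- TRUE
      ep$reject_reason <- reason
      log[[length(log) + 1L]] <- data.frame(
        subject_id = ep$subject_id, condition = ep$condition,
        epoch_index = ep$epoch_index, reason = reason,
        channel = channel, value = value, stringsAsFactors = FALSE)
    }
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(subject_id = character(), condition = character(),
               epoch_index = integer(), reason = character(),
               channel = character(), value = numeric())
  list(kept = kept, log = log)
}

#' Full preprocessing chain for one recording
#'
#' Applies the fixed pipeline order: band-pass filter on the continuous
#' recording, common-average re-reference, fixed-length epoching, threshold
#' artifact rejection.
#'
#' @inheritParams bandpass_filter
#' @inheritParams segment_epochs
#' @inheritParams reject_artifacts
#' @return As [reject_artifacts()].
#' @export
preprocess_recording <- function(rec, low_hz = 2, high_hz = 20, length_s = 2,
                                 amp_threshold_uv = 100, var_threshold = 500,
                                 manual_exclusions = NULL) {
  rec <- bandpass_filter(rec, low_hz, high_hz)
  rec <- rereference_average(rec)
  eps <- segment_epochs(rec, length_s)
  reject_artifacts(eps, amp_threshold_uv, var_threshold, manual_exclusions)
}
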