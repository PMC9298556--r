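#' Construct an EEG recording object
#'
#' A lightweight container for one subject's multichannel recording:
#' a 16 x T signal matrix in microvolts, the sampling rate, a subject id and
#' a binary class label (1 = case, 0 = control). Channels are always stored
#' in the canonical [EEG_MONTAGE] order.
#'
#' @param data numeric matrix, 16 rows (channels) by T columns (samples), in uV.
#' @param fs sampling rate in Hz.
#' @param subject_id character scalar.
#' @param label integer 0 or 1 (may be `NA` for unlabeled data).
#' @param channel_names character vector of 16 names; defaults to the montage.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, subject_id = "S0", label = NA_integer_,
                          channel_names = EEG_MONTAGE) {
  data <- as.matrix(data)
  if (nrow(data) != N_CHANNELS)
    stop("expected ", N_CHANNELS, " channels, got ", nrow(data), call. = FALSE)
  if (length(channel_names) != N_CHANNELS || anyDuplicated(channel_names))
    stop("channel_names must be 16 unique names", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be positive", call. = FALSE)
  if (!all(is.finite(data))) stop("non-finite samples in recording", call. = FALSE)
  rownames(data) <- channel_names
  structure(
    list(subject_id = as.character(subject_id),
         label = if (is.na(label)) NA_integer_ else as.integer(label),
         fs = as.numeric(fs),
         channel_names = as.character(channel_names),
         data = data),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, label %s, %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, ifelse(is.na(x$label), "NA", x$label),
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

duration_s <- function(rec) ncol(rec$data) / rec$fs
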