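#' Continuous multichannel EEG recording
#'
#' Lightweight in-memory container shared by all pipeline stages:
#' a channels x samples matrix in microvolts plus sampling rate, unique
#' channel labels and the subject identifier. Scalp positions are looked
#' up from the built-in 10-20 montage when the labels are standard sites;
#' non-standard labels require explicitly supplied positions.
#'
#' @param data Numeric matrix, channels x samples, uV.
#' @param fs Sampling frequency, Hz.
#' @param channel_labels Character vector, one unique label per row.
#' @param positions Optional data frame of positions (as returned by
#'   [montage_1020()]); defaults to the built-in montage lookup.
#' @param subject_id Subject identifier string.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels, positions = NULL,
                          subject_id = "S01") {
  data <- as.matrix(data)
  if (length(channel_labels) == 0L) stop("format error: empty channel list")
  if (nrow(data) != length(channel_labels))
    stop("format error: data rows (", nrow(data),
         ") do not match channel labels (", length(channel_labels), ")")
  if (anyDuplicated(channel_labels))
    stop("format error: duplicated channel labels")
  if (!is.numeric(fs) || fs <= 0) stop("format error: fs must be > 0")
  if (is.null(positions)) positions <- montage_1020(channel_labels)
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 positions = positions, subject_id = subject_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

# Samples are addressed with round(seconds * fs), applied uniformly by
# every stage (rounding, not truncation).
seconds_to_sample <- function(seconds, fs) as.integer(round(seconds * fs))
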