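#' Broadband zero-phase filtering of a continuous recording
#'
#' High-pass and low-pass Butterworth sections (default order 4 each)
#' applied forward-backward (`signal::filtfilt`), so the output is
#' zero-phase. The channel mean (DC) is removed before filtering. Band
#' edges are conventional -3 dB points; at `order = 4` the
#' forward-backward response is about -17 dB at 50 Hz and within 5% of
#' unity through the theta/alpha range.
#'
#' @param recording An [eeg_recording()].
#' @param low,high Band edges in Hz (defaults 0.3 and 40).
#' @param order Butterworth order of each section.
#' @return The filtered [eeg_recording()].
#' @export
bandpass_broad <- function(recording, low = 0.3, high = 40, order = 4) {
  stopifnot(inherits(recording, "eeg_recording"))
  nyq <- recording$fs / 2
  if (!(0 < low && low < high)) stop("parameter error: need 0 < low < high")
  if (high >= nyq)
    stop("parameter error: high edge (", high, " Hz) must be below the ",
         "Nyquist frequency (", nyq, " Hz)")
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  for (i in seq_len(nrow(recording$data))) {
    x <- recording$data[i, ]
    x <- x - mean(x)
    x <- signal::filtfilt(hp, x)
    x <- signal::filtfilt(lp, x)
    recording$data[i, ] <- x
  }
  recording
}

#' Cut event-locked epochs from a continuous recording
#'
#' One epoch per shot event, covering the half-open window \[-6, +4) s
#' around shot release (`round(10 * fs)` samples; the sample at relative
#' time 0 is the shot-release sample). Events too close to the recording
#' edges for a full window are dropped and logged.
#'
#' @param recording A (filtered) [eeg_recording()].
#' @param events Event table with columns `subject`, `trial`, `onset_s`;
#'   only rows matching `recording$subject_id` are used.
#' @param window Epoch window in seconds relative to the event.
#' @return Object of class `eeg_epochs`: `data` (trials x channels x
#'   samples), `fs`, `window`, `t0` (1-based index of the event sample),
#'   `trials` (subject/trial/onset rows kept), `channel_labels`,
#'   `artifact_bad` (logical per trial, all `FALSE` initially) and
#'   `dropped` (logged out-of-bounds events).
#' @export
epoch_extract <- function(recording, events, window = c(-6, 4)) {
  stopifnot(inherits(recording, "eeg_recording"), window[1] < window[2])
  ev <- events[events$subject == recording$subject_id, , drop = FALSE]
  if (nrow(ev) == 0L)
    stop("pipeline error: no events for subject ", recording$subject_id)
  fs <- recording$fs
  n <- ncol(recording$data)
  n_samp <- seconds_to_sample(window[2] - window[1], fs)
  onset_sample <- seconds_to_sample(ev$onset_s, fs)
  start <- onset_sample + seconds_to_sample(window[1], fs)
  stop_ <- start + n_samp - 1L
  usable <- start >= 1L & stop_ <= n
  dropped <- ev[!usable, , drop = FALSE]
  ev <- ev[usable, , drop = FALSE]
  if (nrow(ev) == 0L)
    stop("pipeline error: zero usable events (all too close to recording ",
         "edges)")
  start <- start[usable]
  data <- array(0, dim = c(nrow(ev), nrow(recording$data), n_samp),
                dimnames = list(NULL, recording$channel_labels, NULL))
  for (i in seq_len(nrow(ev))) {
    data[i, , ] <- recording$data[, start[i]:(start[i] + n_samp - 1L)]
  }
  structure(list(data = data, fs = fs, window = window,
                 t0 = 1L - seconds_to_sample(window[1], fs),  # tau(j) = (j - t0)/fs

                 trials = ev, channel_labels = recording$channel_labels,
                 artifact_bad = rep(FALSE, nrow(ev)), dropped = dropped),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(paste0("<eeg_epochs> %d trials x %d channels x %d samples ",
                     "@ %g Hz, window [%g, %g) s, %d marked bad\n"),
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              x$window[1], x$window[2], sum(x$artifact_bad)))
  invisible(x)
}

# Sample indices of a half-open time window [w1, w2) relative to the
# event, with an edge-guard check against filter transients.
window_indices <- function(epochs, win, edge_guard_s = 0) {
  if (win[1] < epochs$window[1] + edge_guard_s ||
      win[2] > epochs$window[2] - edge_guard_s)
    stop("parameter error: window [", win[1], ", ", win[2], ") violates ",
         "the ", edge_guard_s, " s edge guard of the [", epochs$window[1],
         ", ", epochs$window[2], ") s epoch")
  a <- epochs$t0 + seconds_to_sample(win[1], epochs$fs)
  b <- epochs$t0 + seconds_to_sample(win[2], epochs$fs) - 1L
  a:b
}

#' Threshold-based artifact rejection
#'
#' An epoch is marked bad when, within the analysis-relevant pre-shot
#' span (default \[-6, 0\] s), any channel exceeds the peak-to-peak
#' amplitude threshold, exceeds the sample-to-sample gradient threshold,
#' or is flat (peak-to-peak below `flat_thresh`). Post-shot artifacts
#' (recoil, movement) do not discard a trial because only pre-shot data
#' enter the analysis. Detection is idempotent: re-running it never
#' un-marks an epoch.
#'
#' @param epochs An [epoch_extract()] result.
#' @param amp_thresh Peak-to-peak amplitude threshold, uV.
#' @param grad_thresh Sample-to-sample gradient threshold, uV/sample.
#' @param flat_thresh Flat-channel peak-to-peak floor, uV.
#' @param span Time span (s, relative to the event) the rules apply to.
#' @return `epochs` with `artifact_bad` updated and a `rejections`
#'   element (per-subject counts of checked/rejected trials).
#' @export
artifact_detect <- function(epochs, amp_thresh = 100, grad_thresh = 50,
                            flat_thresh = 0.5, span = c(-6, 0)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  idx <- window_indices(epochs, span)
  n_trials <- dim(epochs$data)[1]
  bad <- epochs$artifact_bad
  for (i in seq_len(n_trials)) {
    seg <- epochs$data[i, , idx, drop = TRUE]
    if (is.null(dim(seg))) seg <- matrix(seg, nrow = 1)
    p2p <- apply(seg, 1, function(v) diff(range(v)))
    grad <- apply(seg, 1, function(v) max(abs(diff(v))))
    if (any(p2p > amp_thresh) || any(grad > grad_thresh) ||
        any(p2p < flat_thresh)) {
      bad[i] <- TRUE
    }
  }
  if (all(bad))
    stop("pipeline error: all epochs rejected; review the artifact ",
         "thresholds (amp ", amp_thresh, " uV, grad ", grad_thresh,
         " uV/sample, flat ", flat_thresh, " uV)")
  epochs$artifact_bad <- bad
  counts <- table(epochs$trials$subject, bad)
  epochs$rejections <- data.frame(
    subject = unique(epochs$trials$subject),
    n_trials = as.vector(table(epochs$trials$subject)),
    n_rejected = as.vector(tapply(bad, epochs$trials$subject, sum)))
  epochs
}
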