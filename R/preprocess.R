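# Signal conditioning and windowing: zero-phase Butterworth filtering,
# common average referencing, per-recording z-scoring, and 5 s / 50%
# overlap segmentation with seizure-overlap labeling.
#
# Processing order (applied by preprocess_recording): band-pass -> notch
# -> CAR -> z-score -> segmentation.

#' Zero-phase band-pass and notch filtering
#'
#' Fourth-order Butterworth band-pass (default 0.5-40 Hz) applied
#' forward-backward (zero phase; effective order 8), followed by narrow
#' Butterworth band-stop notches (2 Hz wide) at the recording's mains
#' frequency and its first harmonic (when below Nyquist).
#'
#' @param rec an `eeg_recording` (256 Hz for the standard pipeline).
#' @param band length-2 pass band in Hz.
#' @param notch_width_hz total width of each band-stop notch.
#' @return filtered `eeg_recording`.
#' @export
filter_recording <- function(rec, band = c(0.5, 40), notch_width_hz = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate_hz
  if (fs < 2 * band[2]) {
    stop("sampling rate ", fs, " Hz too low for a ", band[2], " Hz pass band")
  }
  nyq <- fs / 2
  bp <- signal::butter(4, band / nyq, type = "pass")
  notches <- list()
  for (f0 in c(rec$line_noise_hz, 2 * rec$line_noise_hz)) {
    if (f0 + notch_width_hz / 2 < nyq) {
      notches[[length(notches) + 1L]] <-
        signal::butter(2, c(f0 - notch_width_hz / 2,
                            f0 + notch_width_hz / 2) / nyq, type = "stop")
    }
  }
  for (ch in seq_len(nrow(rec$signal))) {
    x <- filtfilt_zp(bp, rec$signal[ch, ])
    for (nf in notches) x <- filtfilt_zp(nf, x)
    rec$signal[ch, ] <- x
  }
  rec
}

#' Common average reference
#'
#' Subtracts the instantaneous across-channel mean from every channel, so
#' the across-channel mean of the output is zero at every sample.
#'
#' @param rec an `eeg_recording` with at least two channels.
#' @return re-referenced `eeg_recording`.
#' @export
rereference_car <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$signal) < 2L) stop("CAR requires at least two channels")
  rec$signal <- sweep(rec$signal, 2, colMeans(rec$signal), "-")
  rec
}

#' Per-channel z-score normalization over the continuous recording
#'
#' x' = (x - mu) / (sigma + eps) with mu, sigma the per-recording channel
#' mean and (population) standard deviation; eps guards constant
#' channels.
#'
#' @param rec an `eeg_recording`.
#' @param eps stabilizer added to sigma (default 1e-8).
#' @return normalized `eeg_recording`.
#' @export
normalize_zscore <- function(rec, eps = 1e-8) {
  stopifnot(inherits(rec, "eeg_recording"))
  mu <- rowMeans(rec$signal)
  sdv <- sqrt(rowMeans((rec$signal - mu)^2))
  rec$signal <- (rec$signal - mu) / (sdv + eps)
  rec
}

#' Segment a recording into labeled, overlapping windows
#'
#' Windows of `window_s` seconds at `hop_s` hop, fully contained in the
#' recording (no partial final window). Each window's `overlap_frac` is
#' the fraction of its duration covered by annotated seizure intervals
#' (half-open `[onset, offset)`); windows with `overlap_frac >= 0.5` are
#' labeled seizure.
#'
#' @param rec a preprocessed `eeg_recording`.
#' @param intervals data.frame with `onset_s`, `offset_s` for this
#'   session (e.g. the matching rows of [parse_annotations()]); may be
#'   empty or NULL.
#' @param window_s,hop_s window and hop durations in seconds.
#' @param keep_signal if FALSE the `segments` tensor is dropped
#'   (labels/times only), saving memory.
#' @return a `segment_set`: list with `segments`
#'   `[n_segments x n_channels x window_samples]`, `start_times_s`,
#'   `labels`, `overlap_frac`, `subject_id`, `session_id`,
#'   `channel_labels`, `window_s`, `hop_s`, `fs_hz`.
#' @export
segment_and_label <- function(rec, intervals = NULL, window_s = 5,
                              hop_s = 2.5, keep_signal = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate_hz
  wlen <- round(window_s * fs)
  dur <- rec_duration_s(rec)
  if (dur < window_s) {
    warning("recording shorter than one window; empty segment set")
    starts <- numeric(0)
  } else {
    starts <- seq(0, dur - window_s + 1e-9, by = hop_s)
    starts <- starts[starts + window_s <= dur + 1e-9]
  }
  n <- length(starts)
  ofrac <- numeric(n)
  if (!is.null(intervals) && nrow(intervals) > 0 && n > 0) {
    for (i in seq_len(n)) {
      w0 <- starts[i]; w1 <- starts[i] + window_s
      cov <- sum(pmax(0, pmin(w1, intervals$offset_s) -
                         pmax(w0, intervals$onset_s)))
      ofrac[i] <- min(1, cov / window_s)
    }
  }
  segs <- NULL
  if (keep_signal && n > 0) {
    segs <- array(0, dim = c(n, nrow(rec$signal), wlen))
    for (i in seq_len(n)) {
      i0 <- round(starts[i] * fs) + 1L
      segs[i, , ] <- rec$signal[, i0:(i0 + wlen - 1L), drop = FALSE]
    }
  }
  structure(list(segments = segs,
                 start_times_s = starts,
                 labels = as.integer(ofrac >= 0.5),
                 overlap_frac = ofrac,
                 subject_id = rep(rec$subject_id, n),
                 session_id = rep(rec$session_id, n),
                 channel_labels = rec$channel_labels,
                 window_s = window_s, hop_s = hop_s, fs_hz = fs),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d windows of %g s (hop %g s), %d channels, %d seizure-labeled\n",
              length(x$start_times_s), x$window_s, x$hop_s,
              length(x$channel_labels), sum(x$labels)))
  invisible(x)
}

#' Full conditioning chain for one recording
#'
#' band-pass -> notch -> CAR -> z-score, then segmentation/labeling.
#'
#' @inheritParams segment_and_label
#' @inheritParams filter_recording
#' @return a `segment_set`.
#' @export
preprocess_recording <- function(rec, intervals = NULL, band = c(0.5, 40),
                                 window_s = 5, hop_s = 2.5) {
  rec <- filter_recording(rec, band = band)
  rec <- rereference_car(rec)
  rec <- normalize_zscore(rec)
  segment_and_label(rec, intervals, window_s = window_s, hop_s = hop_s)
}

#' Number of fully-contained analysis windows in a duration
#'
#' `floor((T - window_s)/hop_s) + 1` for `T >= window_s`, else 0.
#'
#' @param duration_s recording duration in seconds.
#' @param window_s,hop_s window and hop in seconds.
#' @return integer window count.
#' @export
n_windows <- function(duration_s, window_s = 5, hop_s = 2.5) {
  if (duration_s < window_s) return(0L)
  as.integer(floor((duration_s - window_s) / hop_s + 1e-9) + 1L)
}
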