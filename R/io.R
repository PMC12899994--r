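# Ingestion of EEG recordings and seizure annotation tables.
#
# Conventions: times are seconds from session start; seizure intervals are
# half-open [onset, offset); signals are microvolts unless `unit_scale`
# says otherwise.

#' Construct an EEG recording object
#'
#' @param subject_id,session_id identifiers.
#' @param channel_labels ordered, unique montage labels (e.g. "FT9-FT10").
#' @param sampling_rate_hz positive sampling rate.
#' @param signal numeric matrix `[n_channels x n_samples]`, microvolts.
#' @param line_noise_hz mains frequency, 50 or 60.
#' @return an object of class `eeg_recording`.
#' @export
new_recording <- function(subject_id, session_id, channel_labels,
                          sampling_rate_hz, signal, line_noise_hz = 60) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1L)
  if (nrow(signal) != length(channel_labels)) {
    stop("signal rows (", nrow(signal), ") must match channel labels (",
         length(channel_labels), ")")
  }
  if (anyDuplicated(channel_labels)) {
    stop("duplicated channel label(s): ",
         paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "))
  }
  if (!is_scalar_number(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a positive number")
  }
  if (!line_noise_hz %in% c(50, 60)) stop("line_noise_hz must be 50 or 60")
  structure(list(subject_id = as.character(subject_id),
                 session_id = as.character(session_id),
                 channel_labels = as.character(channel_labels),
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 signal = signal,
                 line_noise_hz = line_noise_hz),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s: %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$session_id, nrow(x$signal), ncol(x$signal),
              x$sampling_rate_hz, ncol(x$signal) / x$sampling_rate_hz))
  invisible(x)
}

rec_duration_s <- function(rec) ncol(rec$signal) / rec$sampling_rate_hz

#' Read one EEG session from an EDF file
#'
#' Unreadable or truncated files raise an integrity error (callers such as
#' [run_pipeline()] catch it, skip the file, and log the event). In strict
#' mode the sampling rate must equal `expected_fs_hz` and the header's
#' record count must match the data actually present.
#'
#' @param path EDF file.
#' @param line_noise_hz mains frequency of the acquisition site (50 or 60).
#' @param subject_id,session_id identifiers; default from the file name.
#' @param strict verify sampling rate and duration continuity.
#' @param expected_fs_hz required rate in strict mode.
#' @param unit_scale multiplier applied to the stored physical values to
#'   obtain microvolts (1 when the EDF is already in uV).
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, line_noise_hz = 60,
                           subject_id = NULL, session_id = NULL,
                           strict = TRUE, expected_fs_hz = 256,
                           unit_scale = 1) {
  edf <- read_edf(path)
  base <- sub("\\.edf$", "", basename(path), ignore.case = TRUE)
  if (strict) {
    if (abs(edf$fs_hz - expected_fs_hz) > 1e-9) {
      stop("sampling rate ", edf$fs_hz, " Hz != expected ", expected_fs_hz,
           " Hz in ", path)
    }
  }
  labs <- edf$channel_labels
  dup <- duplicated(labs)
  if (any(dup)) {
    message("dropping ", sum(dup), " exact-duplicate channel label(s) in ",
            basename(path), ": ", paste(unique(labs[dup]), collapse = ", "))
    edf$signal <- edf$signal[!dup, , drop = FALSE]
    labs <- labs[!dup]
  }
  new_recording(subject_id = subject_id %||% sub("_.*$", "", base),
                session_id = session_id %||% base,
                channel_labels = labs,
                sampling_rate_hz = edf$fs_hz,
                signal = edf$signal * unit_scale,
                line_noise_hz = line_noise_hz)
}

#' Parse a seizure annotation table
#'
#' Canonical dialect: CSV with header `session,onset_s,offset_s`. Intervals
#' are half-open `[onset, offset)` seconds from session start; overlapping
#' or touching intervals within a session are merged and sorted.
#'
#' @param path CSV file path.
#' @param known_sessions optional character vector; rows whose session is
#'   not listed produce a warning (the row is kept).
#' @return data.frame with columns `session_id`, `onset_s`, `offset_s`.
#' @export
parse_annotations <- function(path, known_sessions = NULL) {
  empty <- data.frame(session_id = character(), onset_s = numeric(),
                      offset_s = numeric(), stringsAsFactors = FALSE)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) return(empty)
  need <- c("session", "onset_s", "offset_s")
  if (!all(need %in% names(raw))) {
    stop("annotation file must have columns ", paste(need, collapse = ","))
  }
  if (any(!is.finite(raw$onset_s)) || any(!is.finite(raw$offset_s))) {
    stop("non-numeric onset/offset in ", path)
  }
  if (any(raw$offset_s <= raw$onset_s)) {
    bad <- which(raw$offset_s <= raw$onset_s)[1]
    stop("offset_s <= onset_s at row ", bad, " of ", path)
  }
  if (any(raw$onset_s < 0)) stop("negative onset_s in ", path)
  if (!is.null(known_sessions)) {
    unk <- setdiff(unique(raw$session), known_sessions)
    if (length(unk)) {
      warning("annotations reference unknown session(s): ",
              paste(unk, collapse = ", "))
    }
  }
  merged <- lapply(split(raw, raw$session), function(d) {
    d <- d[order(d$onset_s), , drop = FALSE]
    on <- d$onset_s[1]; off <- d$offset_s[1]
    out_on <- numeric(); out_off <- numeric()
    for (i in seq_len(nrow(d))[-1]) {
      if (d$onset_s[i] <= off) {
        off <- max(off, d$offset_s[i])
      } else {
        out_on <- c(out_on, on); out_off <- c(out_off, off)
        on <- d$onset_s[i]; off <- d$offset_s[i]
      }
    }
    data.frame(session_id = d$session[1],
               onset_s = c(out_on, on), offset_s = c(out_off, off),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out[order(out$session_id, out$onset_s), , drop = FALSE]
}

#' Parse a CHB-MIT style "summary.txt" annotation file
#'
#' Adapter for the per-subject summary dialect (`File Name:` blocks with
#' `Seizure [n ]Start Time:`/`End Time:` lines in seconds). Returns the
#' same merged table as [parse_annotations()].
#'
#' @param path summary text file.
#' @return data.frame with `session_id`, `onset_s`, `offset_s`.
#' @export
parse_chb_summary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  session <- NA_character_
  rows <- list()
  starts <- numeric()
  for (ln in lines) {
    if (grepl("^\\s*File Name\\s*:", ln)) {
      session <- sub("\\.edf\\s*$", "",
                     trimws(sub("^.*?:", "", ln)), ignore.case = TRUE)
    } else if (grepl("Seizure.*Start Time\\s*:", ln)) {
      starts <- c(starts, as.numeric(gsub("[^0-9.]", "",
                                          sub("^.*?:", "", ln))))
    } else if (grepl("Seizure.*End Time\\s*:", ln)) {
      off <- as.numeric(gsub("[^0-9.]", "", sub("^.*?:", "", ln)))
      on <- starts[length(starts)]
      rows[[length(rows) + 1L]] <- data.frame(
        session = session, onset_s = on, offset_s = off,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(session_id = character(), onset_s = numeric(),
                      offset_s = numeric(), stringsAsFactors = FALSE))
  }
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(do.call(rbind, rows), tmp, row.names = FALSE)
  parse_annotations(tmp)
}

#' Channels common to all recordings, in canonical order
#'
#' Returns the channel labels present in every recording, ordered as in
#' the first recording (the canonical order), so feature columns align
#' across sessions.
#'
#' @param recordings list of `eeg_recording` objects.
#' @return character vector of channel labels.
#' @export
intersect_channels <- function(recordings) {
  stopifnot(length(recordings) >= 1L)
  common <- Reduce(intersect, lapply(recordings, function(r) r$channel_labels))
  common <- recordings[[1]]$channel_labels[
    recordings[[1]]$channel_labels %in% common]
  if (!length(common)) stop("no channel is common to all recordings")
  common
}

#' Resample a recording to a target rate
#'
#' Polyphase resampling (rational factor, FIR anti-aliasing) applied per
#' channel; duration is preserved to within one sample period.
#'
#' @param rec an `eeg_recording`.
#' @param target_hz positive target rate.
#' @return resampled `eeg_recording`.
#' @export
resample_recording <- function(rec, target_hz) {
  stopifnot(inherits(rec, "eeg_recording"), target_hz > 0)
  if (abs(target_hz - rec$sampling_rate_hz) < 1e-9) return(rec)
  pq <- rational_approx(target_hz / rec$sampling_rate_hz)
  out <- t(apply(rec$signal, 1, resample_poly, p = pq["p"], q = pq["q"]))
  new_recording(rec$subject_id, rec$session_id, rec$channel_labels,
                target_hz, out, rec$line_noise_hz)
}
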