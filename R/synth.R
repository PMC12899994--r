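# Synthetic multi-subject EEG cohorts with annotated ictal intervals.
#
# The generator emulates the statistical structure the detection pipeline
# assumes: 1/f background with a posterior-dominant alpha rhythm, and
# ictal episodes expressed as amplitude-modulated theta rhythmicity with
# a raised amplitude envelope, strongest on a small set of focus channels.

# 23 unique bipolar 10-20 montage labels (CHB-MIT style double banana,
# de-duplicated, plus an occipital transverse derivation).
chb_montage_23 <- function() {
  c("FP1-F7", "F7-T7", "T7-P7", "P7-O1",
    "FP1-F3", "F3-C3", "C3-P3", "P3-O1",
    "FP2-F4", "F4-C4", "C4-P4", "P4-O2",
    "FP2-F8", "F8-T8", "T8-P8", "P8-O2",
    "FZ-CZ", "CZ-PZ", "P7-T7", "T7-FT9",
    "FT9-FT10", "FT10-T8", "O1-O2")
}

#' Parameters for the synthetic EEG cohort generator
#'
#' Defaults define the desk-scale study conditions used throughout the
#' package's tests: 6 seizure-positive plus 3 seizure-free subjects, one
#' 600 s session each, 23 bipolar channels at 256 Hz, and two 20-40 s
#' seizures per positive subject, which yields a seizure-segment
#' prevalence of about 10% of 5 s windows (the 8-12% band typical of
#' curated scalp-EEG corpora).
#'
#' @param n_subjects number of seizure-positive subjects.
#' @param n_free_subjects seizure-free subjects (false-alarm assessment).
#' @param sessions_per_subject sessions per subject.
#' @param session_length_s session duration, seconds.
#' @param n_channels number of channels (first `n` of the 23-label montage).
#' @param fs_hz sampling rate; the pipeline assumes 256.
#' @param seizures_per_subject seizures per positive subject per session.
#' @param seizure_len_s length-2 range (s) from which seizure durations
#'   are drawn uniformly.
#' @param ictal_theta_gain amplitude of the added 4-8 Hz rhythm, in units
#'   of the channel SD, as `(gain - 1)`; 1 means no added rhythm.
#' @param ictal_amp_gain multiplicative amplitude envelope inside the
#'   seizure; 1 means no amplitude change.
#' @param alpha_gain amplitude of the background 8-13 Hz component in
#'   units of the channel SD; 0 disables it.
#' @param background_slope exponent of the 1/f^slope background spectrum.
#' @param focus_channels labels receiving the full ictal gain; all other
#'   channels receive 25% of the added component.
#' @param rms_uv target background RMS amplitude in microvolts.
#' @param line_noise_hz mains frequency recorded in the metadata.
#' @param seed global seed; per-subject/session streams are derived from it.
#' @return a `synth_params` list.
#' @export
synth_params <- function(n_subjects = 6L,
                         n_free_subjects = 3L,
                         sessions_per_subject = 1L,
                         session_length_s = 600,
                         n_channels = 23L,
                         fs_hz = 256,
                         seizures_per_subject = 2L,
                         seizure_len_s = c(20, 40),
                         ictal_theta_gain = 3,
                         ictal_amp_gain = 1.5,
                         alpha_gain = 1,
                         background_slope = 1,
                         focus_channels = c("FT9-FT10", "T7-P7", "FP1-F3"),
                         rms_uv = 30,
                         line_noise_hz = 60,
                         seed = 42L) {
  seizure_len_s <- as.numeric(unlist(seizure_len_s))
  stopifnot(n_subjects >= 1L, n_free_subjects >= 0L,
            sessions_per_subject >= 1L,
            session_length_s > 0, n_channels >= 2L, n_channels <= 23L,
            fs_hz > 0, seizures_per_subject >= 0L,
            length(seizure_len_s) == 2L, seizure_len_s[1] <= seizure_len_s[2],
            ictal_theta_gain >= 1, ictal_amp_gain >= 1,
            background_slope >= 0, rms_uv > 0)
  labels <- chb_montage_23()[seq_len(n_channels)]
  focus_channels <- intersect(focus_channels, labels)
  if (!length(focus_channels)) focus_channels <- labels[1]
  structure(list(n_subjects = as.integer(n_subjects),
                 n_free_subjects = as.integer(n_free_subjects),
                 sessions_per_subject = as.integer(sessions_per_subject),
                 session_length_s = session_length_s,
                 n_channels = as.integer(n_channels),
                 channel_labels = labels,
                 fs_hz = fs_hz,
                 seizures_per_subject = as.integer(seizures_per_subject),
                 seizure_len_s = seizure_len_s,
                 ictal_theta_gain = ictal_theta_gain,
                 ictal_amp_gain = ictal_amp_gain,
                 alpha_gain = alpha_gain,
                 background_slope = background_slope,
                 focus_channels = focus_channels,
                 rms_uv = rms_uv,
                 line_noise_hz = line_noise_hz,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# 1/f^slope Gaussian noise via spectral shaping, unit SD.
colored_noise <- function(n, slope) {
  w <- stats::rnorm(n)
  if (slope == 0) return(w)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)                 # two-sided frequency index
  shape <- ifelse(f > 0, f^(-slope / 2), 0)
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate one session of background EEG
#'
#' Per channel: 1/f^slope Gaussian noise plus a slowly amplitude-modulated
#' 8-13 Hz alpha component, scaled to `rms_uv`. Deterministic given
#' `params$seed`, `subject_id` and `session_id`.
#'
#' @param params a [synth_params()] object.
#' @param subject_id,session_id identifiers (also used to derive the
#'   per-session random stream).
#' @return an `eeg_recording`.
#' @export
generate_background <- function(params, subject_id = "s01",
                                session_id = NULL) {
  stopifnot(inherits(params, "synth_params"))
  session_id <- session_id %||% paste0(subject_id, "_r01")
  n <- round(params$session_length_s * params$fs_hz)
  tt <- (seq_len(n) - 1) / params$fs_hz
  with_seed(derive_seed(params$seed, paste0("bg:", subject_id, ":", session_id)), {
    sig <- matrix(0, params$n_channels, n)
    for (ch in seq_len(params$n_channels)) {
      x <- colored_noise(n, params$background_slope)
      if (params$alpha_gain > 0) {
        f_alpha <- stats::runif(1, 9, 11)
        env <- 1 + 0.5 * sin(2 * pi * stats::runif(1, 0.05, 0.15) * tt +
                               stats::runif(1, 0, 2 * pi))
        x <- x + params$alpha_gain * env *
          sin(2 * pi * f_alpha * tt + stats::runif(1, 0, 2 * pi)) / sqrt(2)
      }
      sig[ch, ] <- x / stats::sd(x) * params$rms_uv
    }
    new_recording(subject_id, session_id, params$channel_labels,
                  params$fs_hz, sig, params$line_noise_hz)
  })
}

# Raised-cosine taper: 0 -> 1 over `ramp` samples at each end.
edge_taper <- function(n, ramp) {
  ramp <- min(ramp, floor(n / 2))
  w <- rep(1, n)
  if (ramp > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp) / (ramp + 1)))
    w[seq_len(ramp)] <- up
    w[n + 1 - seq_len(ramp)] <- up
  }
  w
}

#' Inject one ictal episode into a recording
#'
#' Inside `[onset_s, offset_s)`, focus channels receive an added 4-8 Hz
#' rhythmic component with slow amplitude modulation, of amplitude
#' `(ictal_theta_gain - 1)` channel SDs, and a multiplicative amplitude
#' envelope rising to `ictal_amp_gain`; both are tapered with raised
#' cosine edges. Non-focus channels receive 25% of the added component
#' and envelope, emulating focal onset with attenuated spread.
#'
#' @param rec an `eeg_recording`.
#' @param onset_s,offset_s seizure interval, seconds (half-open).
#' @param params a [synth_params()] object.
#' @param theta_freq_hz rhythm frequency; default drawn deterministically
#'   from the interval position.
#' @return the modified `eeg_recording`.
#' @export
inject_ictal_event <- function(rec, onset_s, offset_s, params,
                               theta_freq_hz = NULL) {
  stopifnot(inherits(rec, "eeg_recording"), offset_s > onset_s)
  fs <- rec$sampling_rate_hz
  dur <- rec_duration_s(rec)
  if (onset_s < 0 || offset_s > dur + 1e-9) {
    stop("seizure interval [", onset_s, ", ", offset_s,
         ") outside recording duration ", dur, " s")
  }
  theta_freq_hz <- theta_freq_hz %||%
    (4 + (derive_seed(params$seed, sprintf("f:%s:%.3f", rec$session_id,
                                           onset_s)) %% 4000) / 1000)
  i0 <- floor(onset_s * fs) + 1L
  i1 <- min(ceiling(offset_s * fs), ncol(rec$signal))
  idx <- i0:i1
  tt <- (idx - 1) / fs
  taper <- edge_taper(length(idx), ramp = round(min(2, (offset_s - onset_s) / 4) * fs))
  am <- 1 + 0.5 * sin(2 * pi * 0.3 * (tt - onset_s))
  rhythm <- am * sin(2 * pi * theta_freq_hz * tt)
  is_focus <- rec$channel_labels %in% params$focus_channels
  for (ch in seq_len(nrow(rec$signal))) {
    g <- if (is_focus[ch]) 1 else 0.25
    sdc <- stats::sd(rec$signal[ch, ])
    add <- (params$ictal_theta_gain - 1) * g * sdc * rhythm * taper
    scale <- 1 + (params$ictal_amp_gain - 1) * g * taper
    rec$signal[ch, idx] <- rec$signal[ch, idx] * scale + add
  }
  rec
}

# Draw non-overlapping seizure intervals inside [margin, T - margin],
# separated by at least `gap` seconds.
draw_seizure_intervals <- function(n_seiz, session_len, len_range,
                                   margin = 30, gap = 60) {
  if (n_seiz == 0L) return(data.frame(onset_s = numeric(), offset_s = numeric()))
  for (attempt in 1:200) {
    lens <- stats::runif(n_seiz, len_range[1], len_range[2])
    need <- sum(lens) + gap * (n_seiz - 1) + 2 * margin
    if (need > session_len) {
      stop("seizures (", round(sum(lens)), " s + gaps) do not fit in a ",
           session_len, " s session")
    }
    onsets <- sort(stats::runif(n_seiz, margin, session_len - margin - max(lens)))
    offs <- onsets + lens
    ok <- all(diff(onsets) - lens[-n_seiz] >= gap) && all(offs <= session_len - margin)
    if (ok) return(data.frame(onset_s = onsets, offset_s = offs))
  }
  stop("could not place non-overlapping seizure intervals")
}

#' Generate a synthetic cohort on disk
#'
#' Writes one EDF file per session, a cohort-wide `annotations.csv`
#' (canonical `session,onset_s,offset_s` dialect) and a `manifest.json`.
#' Subjects `s01..` are seizure-positive; `f01..` are seizure-free and
#' reserved for false-alarm assessment. Deterministic given
#' `params$seed`: the same parameters yield byte-identical manifests.
#'
#' @param params a [synth_params()] object.
#' @param out_dir writable directory (created if missing).
#' @return the manifest, invisibly (list with `subjects`, `sessions`,
#'   `annotations_file`, `params`).
#' @export
generate_cohort <- function(params, out_dir) {
  stopifnot(inherits(params, "synth_params"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- c(sprintf("s%02d", seq_len(params$n_subjects)),
                if (params$n_free_subjects > 0)
                  sprintf("f%02d", seq_len(params$n_free_subjects)))
  positive <- c(rep(TRUE, params$n_subjects),
                rep(FALSE, params$n_free_subjects))
  sessions <- list()
  ann_rows <- list()
  for (k in seq_along(subjects)) {
    sub <- subjects[k]
    for (r in seq_len(params$sessions_per_subject)) {
      sess <- sprintf("%s_r%02d", sub, r)
      rec <- generate_background(params, sub, sess)
      ints <- if (positive[k]) {
        with_seed(derive_seed(params$seed, paste0("int:", sess)),
                  draw_seizure_intervals(params$seizures_per_subject,
                                         params$session_length_s,
                                         params$seizure_len_s))
      } else data.frame(onset_s = numeric(), offset_s = numeric())
      for (i in seq_len(nrow(ints))) {
        rec <- inject_ictal_event(rec, ints$onset_s[i], ints$offset_s[i], params)
      }
      path <- file.path(out_dir, paste0(sess, ".edf"))
      write_edf(path, rec$signal, rec$channel_labels, params$fs_hz)
      sessions[[sess]] <- list(subject = sub, session = sess,
                               file = basename(path),
                               positive = positive[k],
                               n_seizures = nrow(ints),
                               duration_s = params$session_length_s)
      if (nrow(ints)) {
        ann_rows[[sess]] <- data.frame(session = sess,
                                       onset_s = round(ints$onset_s, 3),
                                       offset_s = round(ints$offset_s, 3))
      }
    }
  }
  ann <- if (length(ann_rows)) do.call(rbind, ann_rows) else
    data.frame(session = character(), onset_s = numeric(), offset_s = numeric())
  ann_path <- file.path(out_dir, "annotations.csv")
  utils::write.csv(ann, ann_path, row.names = FALSE)
  manifest <- list(subjects = subjects,
                   positive = positive,
                   sessions = unname(sessions),
                   annotations_file = "annotations.csv",
                   params = unclass(params))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
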