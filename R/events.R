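# Event-level evaluation: probability smoothing, run grouping, event
# matching, false alarms per 24 h, and the zero-false-alarm frontier.
#
# Matching rule: a true seizure counts as detected when at least one
# predicted event overlaps it in time; each true event counts once
# regardless of how many predictions overlap it.

#' Median-filter smoothing of a probability sequence
#'
#' Running median with symmetric edge padding (edge values reflected
#' including the boundary sample); output has the input length.
#'
#' @param probs numeric vector, time-ordered within one session.
#' @param window odd integer in 3..11.
#' @return smoothed numeric vector.
#' @export
smooth_probabilities <- function(probs, window = 5L) {
  if (window %% 2L == 0L) stop("median window must be odd")
  if (window < 3L || window > 11L) stop("median window must be in 3..11")
  n <- length(probs)
  if (n == 0L) return(probs)
  k <- (window - 1L) %/% 2L
  pad_idx <- c(rev(seq_len(min(k, n))), seq_len(n),
               n + 1L - rev(seq_len(min(k, n))))
  # symmetric padding; if the signal is shorter than k, clamp
  pad_idx <- pmin(pmax(pad_idx, 1L), n)
  if (length(pad_idx) < n + 2L * k) {
    pad_idx <- c(rep(1L, n + 2L * k - length(pad_idx)), pad_idx)
  }
  xp <- probs[pad_idx]
  vapply(seq_len(n), function(i) stats::median(xp[i:(i + window - 1L)]),
         numeric(1))
}

#' Group binary decisions into events
#'
#' Maximal runs of positive decisions with length >= `min_len` segments
#' become predicted events; shorter runs are discarded.
#'
#' @param decisions binary vector, time-ordered within one session.
#' @param start_times_s window start times (seconds).
#' @param window_s window duration.
#' @param min_len minimum run length in segments (default 3).
#' @return data.frame with `start_idx`, `end_idx`, `start_s`, `end_s`.
#' @export
extract_events <- function(decisions, start_times_s = NULL, window_s = 5,
                           min_len = 3L) {
  decisions <- as.integer(decisions)
  if (is.null(start_times_s)) {
    start_times_s <- (seq_along(decisions) - 1) * 2.5
  }
  r <- rle(decisions)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L & r$lengths >= min_len
  data.frame(start_idx = starts[keep], end_idx = ends[keep],
             start_s = start_times_s[starts[keep]],
             end_s = start_times_s[ends[keep]] + window_s)
}

overlaps_any <- function(a0, a1, b0, b1) {
  any(pmax(a0, b0) < pmin(a1, b1))
}

#' Event- and segment-level detection metrics
#'
#' A true event (annotated interval) is detected when >= 1 predicted
#' event overlaps it. Event sensitivity = detected / true events;
#' specificity and precision are segment-level rates (TN/(TN+FP),
#' TP/(TP+FP)); event F1 = 2PR/(P+R) with P the event-level precision
#' (predicted events overlapping truth / predicted events) and R the
#' event sensitivity. Metrics with zero denominators are reported as NA
#' with a flag, never as 0.
#'
#' @param events predicted events ([extract_events()] output).
#' @param truth data.frame with `onset_s`, `offset_s` (may be empty).
#' @param decisions,labels segment-level binary vectors (aligned).
#' @return a `metrics_report` list: `event_sensitivity`, `specificity`,
#'   `precision`, `event_f1`, counts, and `undefined` (names of metrics
#'   with empty denominators).
#' @export
score_events <- function(events, truth, decisions, labels) {
  decisions <- as.integer(decisions); labels <- as.integer(labels)
  stopifnot(length(decisions) == length(labels))
  n_true <- nrow(truth)
  detected <- 0L
  if (n_true > 0) {
    detected <- sum(vapply(seq_len(n_true), function(i) {
      nrow(events) > 0 && overlaps_any(events$start_s, events$end_s,
                                       truth$onset_s[i], truth$offset_s[i])
    }, logical(1)))
  }
  matched_pred <- 0L
  if (nrow(events) > 0 && n_true > 0) {
    matched_pred <- sum(vapply(seq_len(nrow(events)), function(i) {
      overlaps_any(truth$onset_s, truth$offset_s,
                   events$start_s[i], events$end_s[i])
    }, logical(1)))
  }
  tp <- sum(decisions == 1L & labels == 1L)
  fp <- sum(decisions == 1L & labels == 0L)
  tn <- sum(decisions == 0L & labels == 0L)
  undef <- character()
  ev_sens <- if (n_true > 0) detected / n_true else {
    undef <- c(undef, "event_sensitivity"); NA_real_ }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    undef <- c(undef, "specificity"); NA_real_ }
  prec <- if (tp + fp > 0) tp / (tp + fp) else {
    undef <- c(undef, "precision"); NA_real_ }
  ev_prec <- if (nrow(events) > 0) matched_pred / nrow(events) else {
    undef <- c(undef, "event_precision"); NA_real_ }
  ev_f1 <- if (is.finite(ev_prec) && is.finite(ev_sens) &&
               (ev_prec + ev_sens) > 0) {
    2 * ev_prec * ev_sens / (ev_prec + ev_sens)
  } else NA_real_
  structure(list(event_sensitivity = ev_sens, specificity = spec,
                 precision = prec, event_precision = ev_prec,
                 event_f1 = ev_f1,
                 n_true_events = n_true, n_detected = detected,
                 n_pred_events = nrow(events), n_matched_pred = matched_pred,
                 undefined = undef),
            class = "metrics_report")
}

#' False alarms per 24 hours
#'
#' Predicted events with no temporal overlap with any true seizure,
#' normalized to a 24 h monitoring period. Invariant to splitting the
#' monitored period into sessions (counts and hours both add).
#'
#' @param events predicted events.
#' @param truth true intervals (empty for seizure-free data).
#' @param monitored_hours total monitored duration in hours.
#' @return false alarm rate (events / 24 h).
#' @export
fa_per_24h <- function(events, truth, monitored_hours) {
  stopifnot(monitored_hours > 0)
  if (nrow(events) == 0) return(0)
  false_ev <- vapply(seq_len(nrow(events)), function(i) {
    nrow(truth) == 0 || !overlaps_any(truth$onset_s, truth$offset_s,
                                      events$start_s[i], events$end_s[i])
  }, logical(1))
  sum(false_ev) * 24 / monitored_hours
}

#' Per-patient zero-false-alarm frontier
#'
#' For each patient, among models with FA/24 h = 0, the one with the
#' highest event sensitivity; patients for whom no model attains zero
#' false alarms are flagged unattained.
#'
#' @param table data.frame with columns `patient`, `model`,
#'   `sensitivity`, `fa_per_24h`.
#' @return list with `frontier` (one row per patient: best model,
#'   sensitivity, `attained`) and `mean_sensitivity` over attained
#'   patients.
#' @export
zero_fa_frontier <- function(table) {
  stopifnot(all(c("patient", "model", "sensitivity", "fa_per_24h") %in%
                  names(table)))
  rows <- lapply(split(table, table$patient), function(d) {
    ok <- d[d$fa_per_24h == 0, , drop = FALSE]
    if (nrow(ok) == 0) {
      data.frame(patient = d$patient[1], model = NA_character_,
                 sensitivity = NA_real_, attained = FALSE)
    } else {
      best <- ok[which.max(ok$sensitivity), , drop = FALSE]
      data.frame(patient = d$patient[1], model = best$model,
                 sensitivity = best$sensitivity, attained = TRUE)
    }
  })
  frontier <- do.call(rbind, rows)
  rownames(frontier) <- NULL
  list(frontier = frontier,
       mean_sensitivity = mean(frontier$sensitivity[frontier$attained]))
}

#' Event-level evaluation of a LOSO run
#'
#' Per model and fold: calibrated probabilities are median-smoothed per
#' session, thresholded, grouped into events (>= `min_len` consecutive
#' positives), and matched against the annotated intervals of the
#' held-out subject; seizure-free scores (when present) yield FA/24 h.
#'
#' @param loso a `loso_result` from [run_loso()].
#' @param annotations merged interval table ([parse_annotations()]).
#' @param threshold decision threshold on calibrated probabilities.
#' @param smooth_window odd median window (3..11).
#' @param min_len minimum run length per event.
#' @param window_s window duration in seconds.
#' @return data.frame with one row per (model, subject):
#'   `event_sensitivity`, `specificity`, `precision`, `event_f1`,
#'   `fa_per_24h` (free pool; NA when absent), `auc`.
#' @export
evaluate_events <- function(loso, annotations, threshold = 0.5,
                            smooth_window = 5L, min_len = 3L, window_s = 5) {
  rows <- list()
  for (m in names(loso$models)) {
    for (f in loso$models[[m]]) {
      dec <- integer(length(f$calibrated_probs))
      evs <- list()
      for (sess in unique(f$meta$session)) {
        ix <- which(f$meta$session == sess)
        sm <- smooth_probabilities(f$calibrated_probs[ix], smooth_window)
        dec[ix] <- as.integer(sm >= threshold)
        evs[[sess]] <- cbind(session = sess,
                             extract_events(dec[ix], f$meta$start_s[ix],
                                            window_s, min_len))
      }
      truth <- annotations[annotations$session_id %in% f$meta$session, ,
                           drop = FALSE]
      sc <- score_session_events(evs, truth, dec, f$labels)
      fa <- NA_real_
      if (!is.null(f$free)) {
        fa <- fa_free_pool(f$free, annotations, threshold, smooth_window,
                           min_len, window_s)
      }
      rows[[paste(m, f$held_out_subject)]] <-
        data.frame(model = m, patient = f$held_out_subject,
                   event_sensitivity = sc$event_sensitivity,
                   specificity = sc$specificity,
                   precision = sc$precision,
                   event_f1 = sc$event_f1,
                   fa_per_24h = fa,
                   auc = f$metrics[["auc"]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Score events across sessions of one subject: per-session matching,
# aggregated counts.
score_session_events <- function(events_by_session, truth, decisions, labels) {
  det <- 0L; n_true <- 0L; n_pred <- 0L; n_match <- 0L
  for (sess in names(events_by_session)) {
    ev <- events_by_session[[sess]]
    tr <- truth[truth$session_id == sess, , drop = FALSE]
    s <- score_events(ev, tr, decisions = integer(0), labels = integer(0))
    det <- det + s$n_detected; n_true <- n_true + s$n_true_events
    n_pred <- n_pred + s$n_pred_events; n_match <- n_match + s$n_matched_pred
  }
  tp <- sum(decisions == 1L & labels == 1L)
  fp <- sum(decisions == 1L & labels == 0L)
  tn <- sum(decisions == 0L & labels == 0L)
  ev_sens <- if (n_true > 0) det / n_true else NA_real_
  ev_prec <- if (n_pred > 0) n_match / n_pred else NA_real_
  list(event_sensitivity = ev_sens,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       event_f1 = if (is.finite(ev_prec) && is.finite(ev_sens) &&
                      ev_prec + ev_sens > 0) {
         2 * ev_prec * ev_sens / (ev_prec + ev_sens)
       } else NA_real_)
}

# FA/24h of one fold's model on the seizure-free pool: false-event
# counts and monitored hours both aggregate over sessions.
fa_free_pool <- function(free, annotations, threshold, smooth_window,
                         min_len, window_s) {
  n_false <- 0
  hours <- 0
  for (sess in unique(free$meta$session)) {
    ix <- which(free$meta$session == sess)
    sm <- smooth_probabilities(free$probs[ix], smooth_window)
    ev <- extract_events(as.integer(sm >= threshold),
                         free$meta$start_s[ix], window_s, min_len)
    tr <- annotations[annotations$session_id == sess, , drop = FALSE]
    # fa_per_24h at monitored_hours = 24 returns the raw false-event count
    n_false <- n_false + fa_per_24h(ev, tr, 24)
    hours <- hours + (max(free$meta$start_s[ix]) + window_s) / 3600
  }
  n_false * 24 / hours
}

#' Per-fold zero-false-alarm operating points
#'
#' For each model and fold, sweeps the decision threshold and selects
#' the smallest threshold at which the fold's model produces zero false
#' events on the seizure-free pool (maximizing sensitivity among
#' zero-FA operating points). This is the retrospective frontier mode:
#' the operating point is identified post hoc per fold, alongside the
#' fixed-threshold mode of [evaluate_events()].
#'
#' @inheritParams evaluate_events
#' @param thresholds candidate thresholds, swept in increasing order.
#' @return data.frame with one row per (model, patient): `threshold`
#'   (NA when no candidate attains zero false alarms),
#'   `event_sensitivity` at that threshold, `fa_per_24h` (0 when
#'   attained), `attained`.
#' @export
zero_fa_operating_points <- function(loso, annotations,
                                     thresholds = seq(0.5, 0.95, by = 0.05),
                                     smooth_window = 5L, min_len = 3L,
                                     window_s = 5) {
  rows <- list()
  for (m in names(loso$models)) {
    for (f in loso$models[[m]]) {
      if (is.null(f$free)) stop("zero-FA operating points need a scored ",
                                "seizure-free pool (free_fm in run_loso)")
      chosen <- NA_real_; sens <- NA_real_; fa <- NA_real_
      for (th in sort(thresholds)) {
        fa_th <- fa_free_pool(f$free, annotations, th, smooth_window,
                              min_len, window_s)
        if (fa_th == 0) {
          dec <- integer(length(f$calibrated_probs))
          evs <- list()
          for (sess in unique(f$meta$session)) {
            ix <- which(f$meta$session == sess)
            sm <- smooth_probabilities(f$calibrated_probs[ix], smooth_window)
            dec[ix] <- as.integer(sm >= th)
            evs[[sess]] <- extract_events(dec[ix], f$meta$start_s[ix],
                                          window_s, min_len)
          }
          truth <- annotations[annotations$session_id %in% f$meta$session, ,
                               drop = FALSE]
          sc <- score_session_events(evs, truth, dec, f$labels)
          chosen <- th; sens <- sc$event_sensitivity; fa <- 0
          break
        }
      }
      rows[[paste(m, f$held_out_subject)]] <-
        data.frame(model = m, patient = f$held_out_subject,
                   threshold = chosen, event_sensitivity = sens,
                   fa_per_24h = fa, attained = is.finite(chosen))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity / false-alarm operating curve over thresholds
#'
#' Sweeps the decision threshold on calibrated probabilities and reports,
#' per threshold, the aggregate event sensitivity on held-out subjects
#' and the FA/24 h on the seizure-free pool, enabling frontier
#' exploration beyond the fixed 0.5 operating point.
#'
#' @inheritParams evaluate_events
#' @param thresholds probability thresholds to sweep.
#' @return data.frame with `threshold`, `model`, `event_sensitivity`,
#'   `fa_per_24h`.
#' @export
threshold_sweep <- function(loso, annotations,
                            thresholds = seq(0.1, 0.9, by = 0.1),
                            smooth_window = 5L, min_len = 3L, window_s = 5) {
  out <- list()
  for (th in thresholds) {
    ev <- evaluate_events(loso, annotations, threshold = th,
                          smooth_window = smooth_window, min_len = min_len,
                          window_s = window_s)
    agg <- do.call(rbind, lapply(split(ev, ev$model), function(d) {
      data.frame(threshold = th, model = d$model[1],
                 event_sensitivity = mean(d$event_sensitivity, na.rm = TRUE),
                 fa_per_24h = mean(d$fa_per_24h))
    }))
    out[[as.character(th)]] <- agg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
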