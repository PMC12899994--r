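# Per-channel multi-domain feature bank and cross-channel summaries.
#
# Per 5 s single-channel window (32 features): mean, variance, skewness,
# kurtosis, line_length, zcr, hjorth_{activity,mobility,complexity},
# rms, iqr, ptp, tkeo; abs_/rel_ power per canonical band, three band
# ratios, spectral_entropy, median_freq, sef95, one_over_f_slope;
# sampen, permen. Cross-channel: global_max_rms, per-band hemispheric
# lateralization, adjacent-band asymmetry.

#' Feature-extraction configuration
#'
#' @param bands named list of `(lo, hi)` Hz band edges.
#' @param welch_nperseg,welch_overlap Welch PSD segment length (samples)
#'   and fractional overlap.
#' @param sampen_m,sampen_r_factor sample-entropy embedding dimension and
#'   tolerance factor (r = factor x SD).
#' @param permen_order,permen_delay permutation-entropy order and delay.
#' @param sampen_log base of the sample-entropy logarithm ("natural" or
#'   "log2").
#' @return a `feature_config` list.
#' @export
feature_config <- function(bands = list(delta = c(0.5, 4), theta = c(4, 8),
                                        alpha = c(8, 13), beta = c(13, 30),
                                        gamma = c(30, 40)),
                           welch_nperseg = 256L, welch_overlap = 0.5,
                           sampen_m = 2L, sampen_r_factor = 0.2,
                           permen_order = 4L, permen_delay = 1L,
                           sampen_log = c("natural", "log2")) {
  edges <- unlist(bands)
  stopifnot(min(edges) >= 0.5 - 1e-9, max(edges) <= 40 + 1e-9)
  for (b in bands) stopifnot(length(b) == 2L, b[1] < b[2])
  structure(list(bands = bands, welch_nperseg = as.integer(welch_nperseg),
                 welch_overlap = welch_overlap, sampen_m = as.integer(sampen_m),
                 sampen_r_factor = sampen_r_factor,
                 permen_order = as.integer(permen_order),
                 permen_delay = as.integer(permen_delay),
                 sampen_log = match.arg(sampen_log)),
            class = "feature_config")
}

#' Time-domain features of a single-channel window
#'
#' Includes moments, line length, zero-crossing rate, Hjorth parameters
#' (activity = var(x); mobility = sqrt(var(dx)/var(x)); complexity =
#' mobility(dx)/mobility(x), first differences unscaled by fs), RMS,
#' IQR, peak-to-peak, and the mean Teager-Kaiser energy
#' psi[n] = x[n]^2 - x[n-1]x[n+1]. Constant signals return 0 for the
#' ratio-based quantities.
#'
#' @param x numeric vector (>= 3 samples).
#' @return named numeric vector of 13 features.
#' @export
time_domain_features <- function(x) {
  n <- length(x)
  stopifnot(n >= 3L)
  mu <- mean(x)
  v <- stats::var(x)
  vp <- mean((x - mu)^2)                      # population moments
  skew <- if (vp > 0) mean((x - mu)^3) / vp^1.5 else 0
  kurt <- if (vp > 0) mean((x - mu)^4) / vp^2 - 3 else 0
  d1 <- diff(x)
  vd1 <- stats::var(d1)
  mob <- if (v > 0) sqrt(vd1 / v) else 0
  d2 <- diff(d1)
  mob_d <- if (vd1 > 0) sqrt(stats::var(d2) / vd1) else 0
  cmplx <- if (mob > 0) mob_d / mob else 0
  s <- x >= 0
  zcr <- sum(s[-1] != s[-n]) / (n - 1)
  tkeo <- mean(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n])
  c(mean = mu, variance = v, skewness = skew, kurtosis = kurt,
    line_length = sum(abs(d1)), zcr = zcr,
    hjorth_activity = v, hjorth_mobility = mob, hjorth_complexity = cmplx,
    rms = sqrt(mean(x^2)), iqr = stats::IQR(x),
    ptp = max(x) - min(x), tkeo = tkeo)
}

#' Welch power spectral density
#'
#' Hann-windowed, mean over 50%-overlapping segments, one-sided density
#' scaling (power per Hz).
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param nperseg segment length in samples.
#' @param overlap fractional overlap between segments.
#' @return list with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, nperseg = 256L, overlap = 0.5) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nperseg) / nperseg)) # Hann (periodic)
  segs <- vapply(starts, function(s) x[s:(s + nperseg - 1L)] * w,
                 numeric(nperseg))
  ft <- stats::mvfft(segs)
  nf <- nperseg %/% 2L + 1L
  p <- rowMeans(Mod(ft[seq_len(nf), , drop = FALSE])^2)
  scale <- 1 / (fs * sum(w^2))
  p <- p * scale
  if (nf > 2L) p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]  # one-sided
  list(freq = (seq_len(nf) - 1) * fs / nperseg, psd = p)
}

#' Spectral features of a single-channel window
#'
#' Welch PSD (Hann, `welch_nperseg` samples, 50% overlap); absolute band
#' powers (PSD integral over each band), relative powers normalized over
#' the five canonical bands, the ratios theta/alpha, beta/alpha and
#' (beta+gamma)/(alpha+theta), spectral entropy (Shannon entropy of the
#' unit-sum PSD over 0.5-40 Hz divided by log of the bin count, in
#' [0,1]), median frequency, 95% spectral edge, and the least-squares
#' 1/f slope of log10 PSD vs log10 f over 1-40 Hz. An all-zero window
#' returns zeros.
#'
#' @param x numeric vector sampled at `fs` Hz.
#' @param cfg a [feature_config()].
#' @param fs sampling rate (the standard pipeline uses 256).
#' @return named numeric vector of 17 features.
#' @export
spectral_features <- function(x, cfg = feature_config(), fs = 256) {
  bands <- cfg$bands
  zero_out <- c(stats::setNames(rep(0, length(bands)),
                                paste0("abs_", names(bands))),
                stats::setNames(rep(0, length(bands)),
                                paste0("rel_", names(bands))),
                ratio_theta_alpha = 0, ratio_beta_alpha = 0,
                ratio_bg_at = 0, spectral_entropy = 0,
                median_freq = 0, sef95 = 0, one_over_f_slope = 0)
  if (all(x == 0)) return(zero_out)
  ps <- welch_psd(x, fs, cfg$welch_nperseg, cfg$welch_overlap)
  df <- ps$freq[2] - ps$freq[1]
  absb <- vapply(bands, function(b) {
    sel <- ps$freq >= b[1] & ps$freq < b[2]
    sum(ps$psd[sel]) * df
  }, numeric(1))
  names(absb) <- paste0("abs_", names(bands))
  tot <- sum(absb)
  relb <- if (tot > 0) absb / tot else absb * 0
  names(relb) <- paste0("rel_", names(bands))
  g <- function(b) absb[[paste0("abs_", b)]]
  safe_ratio <- function(a, b) if (b > 0) a / b else 0
  in_range <- ps$freq >= 0.5 & ps$freq <= 40
  p <- ps$psd[in_range]
  ptot <- sum(p)
  se <- 0; mf <- 0; sef <- 0
  if (ptot > 0) {
    pn <- p / ptot
    nz <- pn > 0
    se <- -sum(pn[nz] * log(pn[nz])) / log(length(pn))
    cum <- cumsum(pn)
    fr <- ps$freq[in_range]
    mf <- fr[which(cum >= 0.5)[1]]
    sef <- fr[which(cum >= 0.95)[1]]
  }
  fit_sel <- ps$freq >= 1 & ps$freq <= 40 & ps$psd > 0
  slope <- 0
  if (sum(fit_sel) >= 3L) {
    lf <- log10(ps$freq[fit_sel]); lp <- log10(ps$psd[fit_sel])
    slope <- stats::cov(lf, lp) / stats::var(lf)
  }
  c(absb, relb,
    ratio_theta_alpha = safe_ratio(g("theta"), g("alpha")),
    ratio_beta_alpha = safe_ratio(g("beta"), g("alpha")),
    ratio_bg_at = safe_ratio(g("beta") + g("gamma"), g("alpha") + g("theta")),
    spectral_entropy = se, median_freq = mf, sef95 = sef,
    one_over_f_slope = slope)
}

#' Nonlinear features of a single-channel window
#'
#' Sample entropy (Richman-Moorman; Chebyshev distance, self-matches
#' excluded, tolerance r = `sampen_r_factor` x SD(x)); when no template
#' pair matches, the value is capped at log(#template pairs) with a
#' warning. Permutation entropy is the Shannon entropy of ordinal
#' patterns normalized by log(order!), in [0,1].
#'
#' @param x numeric vector (>= 10 samples).
#' @param cfg a [feature_config()].
#' @return named numeric vector `c(sampen, permen)`.
#' @export
nonlinear_features <- function(x, cfg = feature_config()) {
  stopifnot(length(x) >= 10L)
  r <- cfg$sampen_r_factor * stats::sd(x)
  se <- sample_entropy_cpp(as.numeric(x), cfg$sampen_m, r)
  if (isTRUE(se$capped)) {
    warning("sample entropy: no template matches; capped at log(#pairs)")
  }
  sampen <- se$sampen
  if (cfg$sampen_log == "log2") sampen <- sampen / log(2)
  pe <- perm_entropy_cpp(as.numeric(x), cfg$permen_order, cfg$permen_delay)
  c(sampen = sampen, permen = pe)
}

# Hemisphere of a bipolar channel from its first electrode's 10-20
# index: odd digit = left, even = right, no digit (midline) = NA.
channel_side <- function(labels) {
  first <- sub("-.*$", "", labels)
  digits <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", first)))
  ifelse(is.na(digits), NA_character_,
         ifelse(digits %% 2L == 1L, "L", "R"))
}

#' Cross-channel summary features
#'
#' `global_max_rms` (max per-channel RMS); per-band hemispheric
#' lateralization `(L - R)/(L + R + eps)` from summed absolute band
#' powers over left/right channel groups (odd/even 10-20 indices of the
#' first electrode; midline excluded); and adjacent-band asymmetry, the
#' mean over channels of |rel_b - rel_b'| for neighbouring bands.
#'
#' @param per_channel named list (by channel label) of named feature
#'   vectors as produced by the per-channel extractors.
#' @param channel_labels montage labels, same order as `per_channel`.
#' @param bands band names (order defines adjacency).
#' @param eps stabilizer in the lateralization denominator.
#' @return named numeric vector.
#' @export
cross_channel_features <- function(per_channel, channel_labels,
                                   bands = c("delta", "theta", "alpha",
                                             "beta", "gamma"),
                                   eps = 1e-12) {
  stopifnot(length(per_channel) >= 2L,
            length(per_channel) == length(channel_labels))
  out <- c(global_max_rms =
             max(vapply(per_channel, function(f) f[["rms"]], numeric(1))))
  side <- channel_side(channel_labels)
  if (any(side == "L", na.rm = TRUE) && any(side == "R", na.rm = TRUE)) {
    for (b in bands) {
      ab <- vapply(per_channel, function(f) f[[paste0("abs_", b)]], numeric(1))
      L <- sum(ab[which(side == "L")])
      R <- sum(ab[which(side == "R")])
      out[paste0("lateralization_", b)] <- (L - R) / (L + R + eps)
    }
  } else {
    warning("no lateralizable channels; lateralization features omitted")
  }
  for (i in seq_len(length(bands) - 1L)) {
    b1 <- bands[i]; b2 <- bands[i + 1L]
    d <- vapply(per_channel, function(f) {
      abs(f[[paste0("rel_", b1)]] - f[[paste0("rel_", b2)]])
    }, numeric(1))
    out[paste0("asym_", b1, "_", b2)] <- mean(d)
  }
  out
}

# All per-channel features for one window.
channel_features <- function(x, cfg, fs) {
  c(time_domain_features(x), spectral_features(x, cfg, fs),
    suppressWarnings(nonlinear_features(x, cfg)))
}

#' Assemble the named feature matrix for a segment set
#'
#' Concatenates the per-channel banks (column names `{CHANNEL}__{feature}`)
#' and the cross-channel summaries, one row per segment. Labels, subject
#' groups and per-segment metadata (session, start time, seizure-overlap
#' fraction) are carried alongside; `overlap_frac` is metadata, not a
#' model input.
#'
#' @param segs a `segment_set` (with `segments` retained).
#' @param cfg a [feature_config()].
#' @return a `feature_matrix`: list with `values` (numeric matrix),
#'   `feature_names`, `labels`, `groups`, `meta` (data.frame with
#'   `subject`, `session`, `start_s`, `overlap_frac`).
#' @export
build_feature_matrix <- function(segs, cfg = feature_config()) {
  stopifnot(inherits(segs, "segment_set"), !is.null(segs$segments))
  n <- dim(segs$segments)[1]
  stopifnot(n >= 1L)
  labs <- segs$channel_labels
  row1 <- feature_row(segs$segments[1, , , drop = FALSE], labs, cfg, segs$fs_hz)
  vals <- matrix(0, n, length(row1),
                 dimnames = list(NULL, names(row1)))
  vals[1, ] <- row1
  if (n > 1L) {
    for (i in 2:n) {
      vals[i, ] <- feature_row(segs$segments[i, , , drop = FALSE], labs, cfg,
                               segs$fs_hz)
    }
  }
  new_feature_matrix(vals,
                     labels = segs$labels,
                     groups = segs$subject_id,
                     meta = data.frame(subject = segs$subject_id,
                                       session = segs$session_id,
                                       start_s = segs$start_times_s,
                                       overlap_frac = segs$overlap_frac,
                                       stringsAsFactors = FALSE))
}

feature_row <- function(seg, labs, cfg, fs) {
  per_ch <- lapply(seq_along(labs), function(ch) {
    channel_features(as.numeric(seg[1, ch, ]), cfg, fs)
  })
  names(per_ch) <- labs
  flat <- unlist(lapply(seq_along(labs), function(ch) {
    f <- per_ch[[ch]]
    stats::setNames(f, paste0(labs[ch], "__", names(f)))
  }))
  cross <- suppressWarnings(cross_channel_features(per_ch, labs))
  c(flat, cross)
}

new_feature_matrix <- function(values, labels, groups, meta) {
  stopifnot(is.matrix(values), !is.null(colnames(values)),
            !anyDuplicated(colnames(values)),
            nrow(values) == length(labels),
            nrow(values) == length(groups))
  structure(list(values = values,
                 feature_names = colnames(values),
                 labels = as.integer(labels),
                 groups = as.character(groups),
                 meta = meta),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d segments x %d features; %d subjects; %d seizure-labeled\n",
              nrow(x$values), ncol(x$values), length(unique(x$groups)),
              sum(x$labels)))
  invisible(x)
}

# Row-bind feature matrices (same columns).
rbind_feature_matrix <- function(fms) {
  fms <- fms[!vapply(fms, is.null, logical(1))]
  stopifnot(length(fms) >= 1L)
  nm <- fms[[1]]$feature_names
  for (f in fms) stopifnot(identical(f$feature_names, nm))
  new_feature_matrix(do.call(rbind, lapply(fms, function(f) f$values)),
                     labels = unlist(lapply(fms, function(f) f$labels)),
                     groups = unlist(lapply(fms, function(f) f$groups)),
                     meta = do.call(rbind, lapply(fms, function(f) f$meta)))
}

# Column subset preserving metadata.
subset_features <- function(fm, keep) {
  new_feature_matrix(fm$values[, keep, drop = FALSE],
                     fm$labels, fm$groups, fm$meta)
}

# Row subset preserving metadata.
subset_rows <- function(fm, idx) {
  new_feature_matrix(fm$values[idx, , drop = FALSE],
                     fm$labels[idx], fm$groups[idx],
                     fm$meta[idx, , drop = FALSE])
}

#' Write a feature matrix as CSV plus a JSON sidecar schema
#'
#' @param fm a `feature_matrix`.
#' @param path CSV output path; the schema goes to `<path>.schema.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- cbind(fm$meta, label = fm$labels, as.data.frame(fm$values))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(feature_names = fm$feature_names,
                            n_segments = nrow(fm$values),
                            meta_columns = names(fm$meta)),
                       paste0(path, ".schema.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path.
#' @return a `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  schema <- jsonlite::read_json(paste0(path, ".schema.json"),
                                simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.matrix(df[, schema$feature_names, drop = FALSE])
  new_feature_matrix(vals, labels = df$label, groups = df$subject,
                     meta = df[, schema$meta_columns, drop = FALSE])
}
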