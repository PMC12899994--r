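# Minimal EDF (European Data Format) writer/reader for continuous
# multichannel signals. Supports the subset of EDF used by scalp-EEG
# corpora: one fixed sampling rate per file, 1-second data records,
# 16-bit little-endian samples with per-channel linear physical scaling.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too wide: '", x, "'")
  formatC(x, width = width, flag = "-")
}

# Format a physical bound into <= 8 ascii chars and return the exact
# value that the ascii encodes, so writer and reader agree bit-for-bit.
edf_phys_field <- function(x) {
  s <- sprintf("%.6g", x)
  if (nchar(s) > 8) s <- sprintf("%.3g", x)
  if (nchar(s) > 8) stop("cannot encode physical bound in 8 chars: ", x)
  list(text = s, value = as.numeric(s))
}

#' Write a multichannel signal matrix to an EDF file
#'
#' Writes `signal` (one row per channel, microvolts) as 16-bit EDF with
#' one-second data records. The trailing partial second, if any, is
#' dropped with a warning. Physical scaling is chosen per channel from
#' the observed amplitude range, so quantization error is at most one
#' step of `(phys_max - phys_min)/65535`.
#'
#' @param path output file path.
#' @param signal numeric matrix `[n_channels x n_samples]` in microvolts.
#' @param channel_labels character vector, one unique label per row.
#' @param fs_hz sampling rate in Hz (integer; samples per 1-s record).
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signal, channel_labels, fs_hz) {
  stopifnot(is.matrix(signal), nrow(signal) == length(channel_labels))
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  fs <- as.integer(round(fs_hz))
  if (fs <= 0L) stop("fs_hz must be positive")
  n_rec <- nrow(signal)
  n_samples <- ncol(signal)
  n_records <- n_samples %/% fs
  if (n_records < 1L) stop("signal shorter than one EDF data record")
  if (n_records * fs != n_samples) {
    warning("dropping trailing partial second (", n_samples - n_records * fs,
            " samples) when writing EDF")
    signal <- signal[, seq_len(n_records * fs), drop = FALSE]
  }

  dmin <- -32768; dmax <- 32767
  pmin_t <- character(n_rec); pmax_t <- character(n_rec)
  pmin_v <- numeric(n_rec); pmax_v <- numeric(n_rec)
  dig <- matrix(0L, n_rec, ncol(signal))
  for (i in seq_len(n_rec)) {
    a <- max(abs(range(signal[i, ])), 1e-3)
    lo <- edf_phys_field(-a * 1.05)
    hi <- edf_phys_field(a * 1.05)
    pmin_t[i] <- lo$text; pmax_t[i] <- hi$text
    pmin_v[i] <- lo$value; pmax_v[i] <- hi$value
    d <- round((signal[i, ] - pmin_v[i]) / (pmax_v[i] - pmin_v[i]) *
                 (dmax - dmin) + dmin)
    dig[i, ] <- as.integer(pmin(pmax(d, dmin), dmax))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * n_rec
  writeChar(paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad("Startdate 01-JAN-2020 X X X", 80),
    edf_pad("01.01.20", 8),
    edf_pad("00.00.00", 8),
    edf_pad(hdr_bytes, 8),
    edf_pad("", 44),
    edf_pad(n_records, 8),
    edf_pad("1", 8),
    edf_pad(n_rec, 4)
  ), con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(channel_labels, 16)
  field(rep("", n_rec), 80)
  field(rep("uV", n_rec), 8)
  field(pmin_t, 8)
  field(pmax_t, 8)
  field(rep(dmin, n_rec), 8)
  field(rep(dmax, n_rec), 8)
  field(rep("", n_rec), 80)
  field(rep(fs, n_rec), 8)
  field(rep("", n_rec), 32)

  # records: channel-blocked within each 1-s record
  for (r in seq_len(n_records)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Parses the EDF header and 16-bit data records, returning signals in
#' physical units. Only files with a single sampling rate across
#' channels are supported (the layout used by scalp-EEG corpora).
#'
#' @param path EDF file path.
#' @return list with `channel_labels`, `fs_hz`, `signal`
#'   (`[n_channels x n_samples]`, physical units), `n_records`,
#'   `record_duration_s`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd_txt <- function(n) {
    raw <- readBin(con, "raw", n = n)
    if (length(raw) < n) stop("truncated EDF header: ", path)
    trimws(rawToChar(raw))
  }
  rd_txt(8)                       # version
  rd_txt(80); rd_txt(80)          # patient / recording id
  rd_txt(8); rd_txt(8)            # start date / time
  hdr_bytes <- as.integer(rd_txt(8))
  rd_txt(44)
  n_records <- as.integer(rd_txt(8))
  rec_dur <- as.numeric(rd_txt(8))
  ns <- as.integer(rd_txt(4))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header (signal count): ", path)
  fields <- function(width) vapply(seq_len(ns), function(i) rd_txt(width), "")
  labels <- fields(16)
  fields(80)                      # transducer
  fields(8)                       # physical dimension
  pmin <- as.numeric(fields(8))
  pmax <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8))
  dmax <- as.numeric(fields(8))
  fields(80)                      # prefilter
  spr <- as.integer(fields(8))    # samples per record
  fields(32)
  if (length(unique(spr)) != 1L) {
    stop("EDF with per-channel sampling rates is not supported: ", path)
  }
  if (hdr_bytes != 256L + 256L * ns) stop("inconsistent EDF header size: ", path)

  n_per_rec <- spr[1]
  total <- n_records * ns * n_per_rec
  raw <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(raw) < total) stop("truncated EDF data records: ", path)
  sig <- matrix(0, ns, n_records * n_per_rec)
  dat <- array(raw, dim = c(n_per_rec, ns, n_records))
  for (i in seq_len(ns)) {
    sig[i, ] <- as.vector(dat[, i, ]) # concatenated records
  }
  scale <- (pmax - pmin) / (dmax - dmin)
  sig <- sweep(sweep(sig, 1, dmin, "-") * scale, 1, pmin, "+")
  list(channel_labels = labels,
       fs_hz = n_per_rec / rec_dur,
       signal = sig,
       n_records = n_records,
       record_duration_s = rec_dur)
}
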