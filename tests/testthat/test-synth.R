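# Synthetic cohort generator: determinism, spectral structure, ictal
# signature, prevalence.

test_that("background generation is deterministic and spectrally shaped", {
  p <- synth_params(n_subjects = 1, session_length_s = 60, n_channels = 3,
                    seed = 99)
  a <- generate_background(p, "s01")
  b <- generate_background(p, "s01")
  expect_identical(a$signal, b$signal)
  expect_true(all(is.finite(a$signal)))

  # slope 0, no alpha -> flat spectrum (log-log slope ~ 0)
  p0 <- synth_params(n_subjects = 1, session_length_s = 60, n_channels = 3,
                     background_slope = 0, alpha_gain = 0, seed = 99)
  r0 <- generate_background(p0, "s01")
  ps <- welch_psd(r0$signal[1, ], 256, 512)
  sel <- ps$freq >= 1 & ps$freq <= 100
  fit <- stats::lm(log10(ps$psd[sel]) ~ log10(ps$freq[sel]))
  expect_lt(abs(stats::coef(fit)[2]), 0.1)
})

test_that("the alpha component raises relative alpha power over matched noise", {
  base <- synth_params(n_subjects = 1, session_length_s = 60, n_channels = 2,
                       alpha_gain = 0, seed = 5)
  alp <- synth_params(n_subjects = 1, session_length_s = 60, n_channels = 2,
                      alpha_gain = 1.5, seed = 5)
  rel_alpha <- function(rec) {
    sf <- spectral_features(rec$signal[1, 1:1280])
    sf[["rel_alpha"]]
  }
  expect_gt(rel_alpha(generate_background(alp, "s01")),
            rel_alpha(generate_background(base, "s01")))
})

test_that("ictal injection adds theta rhythmicity and amplitude on focus channels", {
  p <- synth_params(n_subjects = 1, session_length_s = 180, seed = 3)
  rec <- generate_background(p, "s01")
  inj <- inject_ictal_event(rec, 60, 100, p)
  ch <- which(rec$channel_labels == p$focus_channels[1])
  inside <- (60 * 256 + 1):(100 * 256)
  outside <- 1:(50 * 256)
  theta <- function(x) {
    ps <- welch_psd(x, 256)
    sum(ps$psd[ps$freq >= 4 & ps$freq < 8])
  }
  expect_gt(theta(inj$signal[ch, inside]) / theta(inj$signal[ch, outside]), 2)
  rms <- function(x) sqrt(mean(x^2))
  expect_gt(rms(inj$signal[ch, inside]), rms(inj$signal[ch, outside]))

  # unit gains leave the signal unchanged
  p1 <- synth_params(n_subjects = 1, session_length_s = 180,
                     ictal_theta_gain = 1, ictal_amp_gain = 1, seed = 3)
  expect_identical(inject_ictal_event(rec, 60, 100, p1)$signal, rec$signal)

  # interval outside the recording errors
  expect_error(inject_ictal_event(rec, 170, 200, p), "outside")
})

test_that("cohort generation is reproducible and structurally correct", {
  p <- synth_params(n_subjects = 2, n_free_subjects = 1,
                    session_length_s = 240, seizures_per_subject = 1,
                    seizure_len_s = c(20, 30), n_channels = 4, seed = 77)
  d1 <- file.path(tempdir(), "synth-repro-1")
  d2 <- file.path(tempdir(), "synth-repro-2")
  unlink(c(d1, d2), recursive = TRUE)
  generate_cohort(p, d1)
  generate_cohort(p, d2)
  m1 <- readBin(file.path(d1, "manifest.json"), "raw",
                file.size(file.path(d1, "manifest.json")))
  m2 <- readBin(file.path(d2, "manifest.json"), "raw",
                file.size(file.path(d2, "manifest.json")))
  expect_identical(m1, m2)
  e1 <- readBin(file.path(d1, "s01_r01.edf"), "raw",
                file.size(file.path(d1, "s01_r01.edf")))
  e2 <- readBin(file.path(d2, "s01_r01.edf"), "raw",
                file.size(file.path(d2, "s01_r01.edf")))
  expect_identical(e1, e2)

  ann <- parse_annotations(file.path(d1, "annotations.csv"))
  expect_true(all(grepl("^s", ann$session_id)))     # free subjects: no rows
  expect_true(all(ann$offset_s > ann$onset_s))
})

test_that("study-condition cohort hits the 8-12% seizure-segment prevalence band", {
  man <- study_manifest()
  ann <- study_annotations()
  pos_sessions <- man$sessions[man$sessions$positive, ]
  lab_sum <- 0L; n_tot <- 0L
  for (i in seq_len(nrow(pos_sessions))) {
    s <- pos_sessions[i, ]
    rec <- read_recording(file.path(study_dir(), s$file),
                          subject_id = s$subject, session_id = s$session)
    segs <- segment_and_label(rec, ann[ann$session_id == s$session, ],
                              keep_signal = FALSE)
    lab_sum <- lab_sum + sum(segs$labels)
    n_tot <- n_tot + length(segs$labels)
  }
  prevalence <- 100 * lab_sum / n_tot
  expect_gte(prevalence, 8)
  expect_lte(prevalence, 12)
})

test_that("generated signals stay clear of the EDF 16-bit range", {
  p <- synth_params(n_subjects = 1, session_length_s = 120, seed = 21)
  rec <- generate_background(p, "s01")
  rec <- inject_ictal_event(rec, 40, 70, p)
  expect_true(all(is.finite(rec$signal)))
  expect_lt(max(abs(rec$signal)), 32000)
})
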