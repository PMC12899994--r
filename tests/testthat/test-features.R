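# Feature bank golden values, closed forms, and invariances.

test_that("time-domain features match hand-computed values", {
  f <- time_domain_features(c(1, 3, 2))
  expect_equal(f[["line_length"]], 3)    # |3-1| + |2-3|
  expect_equal(f[["ptp"]], 2)

  g <- time_domain_features(rep(4, 100))
  expect_equal(g[["variance"]], 0)
  expect_equal(g[["hjorth_activity"]], 0)
  expect_equal(g[["hjorth_mobility"]], 0)
  expect_equal(g[["hjorth_complexity"]], 0)
  expect_equal(g[["zcr"]], 0)
  expect_equal(g[["tkeo"]], 0)
  expect_equal(g[["skewness"]], 0)
})

test_that("sampled-sinusoid closed forms hold within 2%", {
  fs <- 256
  x <- sin(2 * pi * 6 * (0:1279) / fs)
  f <- time_domain_features(x)
  expect_equal(f[["rms"]], 1 / sqrt(2), tolerance = 0.02)
  expect_equal(f[["hjorth_mobility"]], 2 * pi * 6 / fs, tolerance = 0.02)
})

test_that("amplitude scaling transforms features as expected", {
  set.seed(41)
  x <- rnorm(1280)
  c0 <- 3
  a <- c(time_domain_features(x), spectral_features(x),
         suppressWarnings(nonlinear_features(x)))
  b <- c(time_domain_features(c0 * x), spectral_features(c0 * x),
         suppressWarnings(nonlinear_features(c0 * x)))
  expect_equal(b[["variance"]], c0^2 * a[["variance"]])
  expect_equal(b[["rms"]], c0 * a[["rms"]])
  expect_equal(b[["iqr"]], c0 * a[["iqr"]])
  expect_equal(b[["line_length"]], c0 * a[["line_length"]])
  expect_equal(b[["ptp"]], c0 * a[["ptp"]])
  expect_equal(b[["zcr"]], a[["zcr"]])
  expect_equal(b[["permen"]], a[["permen"]])
  expect_equal(b[["rel_theta"]], a[["rel_theta"]], tolerance = 1e-12)
  expect_equal(b[["ratio_beta_alpha"]], a[["ratio_beta_alpha"]],
               tolerance = 1e-12)
  expect_equal(b[["sampen"]], a[["sampen"]], tolerance = 1e-9)
})

test_that("spectral features localize a pure tone and normalize powers", {
  x <- sin(2 * pi * 6 * (0:1279) / 256)
  sf <- spectral_features(x)
  expect_gt(sf[["rel_theta"]], 0.9)
  expect_gte(sf[["median_freq"]], 5.5)
  expect_lte(sf[["median_freq"]], 6.5)
  rels <- sf[paste0("rel_", c("delta", "theta", "alpha", "beta", "gamma"))]
  expect_equal(sum(rels), 1, tolerance = 1e-12)
  expect_true(all(rels >= 0 & rels <= 1))

  expect_true(all(spectral_features(rep(0, 1280)) == 0))
})

test_that("white-noise spectral entropy approaches one", {
  set.seed(42)
  se <- spectral_features(rnorm(8192))[["spectral_entropy"]]
  expect_gt(se, 0.95)
  expect_lte(se, 1)
})

test_that("permutation entropy spans its range", {
  expect_equal(suppressWarnings(nonlinear_features(1:200))[["permen"]], 0)
  set.seed(43)
  expect_gt(nonlinear_features(runif(1280))[["permen"]], 0.95)
})

test_that("sample entropy orders periodic below stochastic signals", {
  set.seed(44)
  tone <- sin(2 * pi * 6 * (0:1279) / 256)
  noise <- rnorm(1280)
  expect_lt(nonlinear_features(tone)[["sampen"]],
            nonlinear_features(noise)[["sampen"]])
})

test_that("sample entropy matches a brute-force R oracle", {
  brute_sampen <- function(x, m = 2, r) {
    nt <- length(x) - m
    A <- 0L; B <- 0L
    for (i in 1:(nt - 1)) {
      for (j in (i + 1):nt) {
        if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
          B <- B + 1L
          if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
        }
      }
    }
    if (A == 0 || B == 0) return(log(nt * (nt - 1) / 2))
    -log(A / B)
  }
  set.seed(45)
  for (rep in 1:5) {
    x <- rnorm(60)
    r <- 0.2 * sd(x)
    got <- ictalarm:::sample_entropy_cpp(x, 2L, r)
    expect_equal(got$sampen, brute_sampen(x, 2, r), tolerance = 1e-12)
  }
})

test_that("sample entropy caps (with a warning) when no templates match", {
  # strictly increasing with unit steps: every template pair differs by
  # >= 1 > r = 0.2 * sd, so no matches exist at either length
  x <- 1:15
  cfg <- feature_config()
  expect_warning(f <- nonlinear_features(x, cfg), "capped")
  expect_equal(f[["sampen"]], log((15 - 2) * (15 - 2 - 1) / 2))
})

test_that("cross-channel summaries behave under symmetry and scaling", {
  set.seed(46)
  x <- rnorm(1280)
  cfg <- feature_config()
  ch <- function(x) channel_features(x, cfg, 256)
  labs <- c("FP1-F3", "FP2-F4", "C3-P3", "C4-P4")
  same <- stats::setNames(lapply(1:4, function(i) ch(x)), labs)
  cc <- cross_channel_features(same, labs)
  for (b in c("delta", "theta", "alpha", "beta", "gamma")) {
    expect_equal(cc[[paste0("lateralization_", b)]], 0, tolerance = 1e-9)
  }
  # one loud channel dominates global_max_rms
  loud <- same
  loud[["C3-P3"]] <- ch(5 * x)
  expect_equal(cross_channel_features(loud, labs)[["global_max_rms"]],
               same[["C3-P3"]][["rms"]] * 5, tolerance = 1e-9)
  # doubling left-channel amplitude raises every lateralization index
  left2 <- stats::setNames(list(ch(2 * x), ch(x), ch(2 * x), ch(x)), labs)
  cc2 <- cross_channel_features(left2, labs)
  for (b in c("delta", "theta", "alpha", "beta", "gamma")) {
    expect_gt(cc2[[paste0("lateralization_", b)]],
              cc[[paste0("lateralization_", b)]])
  }
  # midline-only montage warns and omits lateralization
  mid <- stats::setNames(lapply(1:2, function(i) ch(x)), c("FZ-CZ", "CZ-PZ"))
  expect_warning(ccm <- cross_channel_features(mid, c("FZ-CZ", "CZ-PZ")),
                 "lateraliz")
  expect_false(any(grepl("lateralization", names(ccm))))
})

test_that("the assembled feature matrix is wide, named, and order-equivariant", {
  set.seed(47)
  p <- synth_params(n_subjects = 1, session_length_s = 30, seed = 8)
  rec <- generate_background(p, "s01")
  segs <- segment_and_label(rec, NULL)
  fm <- build_feature_matrix(segs)
  expect_gt(ncol(fm$values), 400)          # 23-channel enumerated bank
  expect_false(anyDuplicated(fm$feature_names) > 0)
  expect_true(all(is.finite(fm$values)))
  expect_true(any(grepl("^FT9-FT10__abs_theta$", fm$feature_names)))
  expect_true("global_max_rms" %in% fm$feature_names)

  # permuting channels permutes columns only
  rec2 <- rec
  perm <- c(2, 1, seq(3, nrow(rec$signal)))
  rec2$signal <- rec$signal[perm, ]
  rec2$channel_labels <- rec$channel_labels[perm]
  fm2 <- build_feature_matrix(segment_and_label(rec2, NULL))
  common <- intersect(fm$feature_names, fm2$feature_names)
  expect_setequal(fm$feature_names, fm2$feature_names)
  expect_equal(fm2$values[, common], fm$values[, common], tolerance = 1e-12)
})

test_that("ictal segments carry elevated focus-channel theta power", {
  p <- synth_params(n_subjects = 1, session_length_s = 120, seed = 9)
  rec <- generate_background(p, "s01")
  rec <- inject_ictal_event(rec, 40, 80, p)
  segs <- preprocess_recording(rec, data.frame(onset_s = 40, offset_s = 80))
  fm <- build_feature_matrix(segs)
  col <- paste0(p$focus_channels[1], "__abs_theta")
  expect_gt(min(fm$values[fm$labels == 1, col]),
            max(fm$values[fm$labels == 0 & fm$meta$overlap_frac == 0, col]) * 0.8)
  expect_gt(mean(fm$values[fm$labels == 1, col]),
            2 * mean(fm$values[fm$labels == 0 & fm$meta$overlap_frac == 0, col]))
})
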