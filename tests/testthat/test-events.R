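# Probability smoothing, event grouping/matching, FA/24h, frontier.

test_that("median smoothing matches hand-worked cases", {
  expect_equal(smooth_probabilities(c(0, 1, 0), 3L), c(0, 0, 0))
  expect_equal(smooth_probabilities(rep(0.4, 10), 5L), rep(0.4, 10))
  expect_error(smooth_probabilities(runif(5), 4L), "odd")
  expect_error(smooth_probabilities(runif(5), 13L), "3..11")
  # an isolated spike never survives any admissible window
  set.seed(71)
  for (w in c(3L, 5L, 7L, 9L, 11L)) {
    for (rep in 1:10) {
      x <- rep(0, 30)
      x[sample(2:29, 1)] <- 1
      expect_true(all(smooth_probabilities(x, w) == 0))
    }
  }
})

test_that("event extraction matches run-length hand cases", {
  ev <- extract_events(c(0, 1, 1, 1, 0, 1, 1, 0))
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start_idx, ev$end_idx), c(2L, 4L))
  expect_equal(ev$start_s, 2.5)
  expect_equal(ev$end_s, 7.5 + 5)

  expect_equal(nrow(extract_events(rep(0, 20))), 0L)

  ev4 <- extract_events(c(1, 1, 1, 1))
  expect_equal(nrow(ev4), 1L)
  expect_equal(ev4$end_idx - ev4$start_idx + 1L, 4L)
})

test_that("event extraction equals a brute-force scan on 1000 random timelines", {
  set.seed(72)
  for (i in 1:1000) {
    n <- sample(5:60, 1)
    dec <- rbinom(n, 1, runif(1, 0.1, 0.7))
    min_len <- sample(1:4, 1)
    got <- extract_events(dec, min_len = min_len)
    want <- brute_force_events(dec, min_len)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start_idx, vapply(want, `[`, integer(1), 1))
      expect_equal(got$end_idx, vapply(want, `[`, integer(1), 2))
    }
  }
})

test_that("event scoring matches an independent brute-force matcher", {
  set.seed(73)
  for (i in 1:200) {
    n <- sample(20:80, 1)
    labels <- rep(0L, n)
    n_seiz <- sample(0:3, 1)
    truth <- data.frame(onset_s = numeric(), offset_s = numeric())
    if (n_seiz > 0) {
      starts <- sort(sample(seq(0, (n - 4) * 2.5, by = 2.5), n_seiz))
      truth <- data.frame(onset_s = starts, offset_s = starts + 7.5)
    }
    dec <- rbinom(n, 1, 0.3)
    times <- (seq_len(n) - 1) * 2.5
    ev <- extract_events(dec, times, min_len = 2L)
    got <- score_events(ev, truth, dec, labels)
    # oracle: direct interval overlap checks
    det <- 0L
    if (nrow(truth)) {
      for (k in seq_len(nrow(truth))) {
        hit <- FALSE
        if (nrow(ev)) {
          for (e in seq_len(nrow(ev))) {
            if (max(ev$start_s[e], truth$onset_s[k]) <
                min(ev$end_s[e], truth$offset_s[k])) hit <- TRUE
          }
        }
        det <- det + hit
      }
      expect_equal(got$event_sensitivity, det / nrow(truth))
    } else {
      expect_true("event_sensitivity" %in% got$undefined)
    }
  }
})

test_that("degenerate event scoring reports NA with flags, not zeros", {
  truth <- data.frame(onset_s = 10, offset_s = 20)
  none <- extract_events(rep(0L, 20))
  got <- score_events(none, truth, rep(0L, 20), c(rep(0L, 16), rep(1L, 4)))
  expect_equal(got$event_sensitivity, 0)
  expect_true(is.na(got$precision))
  expect_true("precision" %in% got$undefined)

  # predictions identical to truth -> all ones
  labels <- c(rep(0L, 5), rep(1L, 6), rep(0L, 9))
  dec <- labels
  times <- (0:19) * 2.5
  ev <- extract_events(dec, times)
  tr <- data.frame(onset_s = 12.5, offset_s = 12.5 + 6 * 2.5)
  perfect <- score_events(ev, tr, dec, labels)
  expect_equal(perfect$event_sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$event_f1, 1)
})

test_that("FA/24h arithmetic and session-split invariance hold", {
  no_truth <- data.frame(onset_s = numeric(), offset_s = numeric())
  none <- extract_events(rep(0L, 10))
  expect_equal(fa_per_24h(none, no_truth, 48), 0)

  two <- data.frame(start_idx = c(1L, 10L), end_idx = c(3L, 12L),
                    start_s = c(0, 100), end_s = c(10, 110))
  expect_equal(fa_per_24h(two, no_truth, 24), 2)
  one <- two[1, ]
  expect_equal(fa_per_24h(one, no_truth, 48), 0.5)

  # splitting the monitored period: counts and hours both add
  whole <- fa_per_24h(two, no_truth, 10)
  split_a <- fa_per_24h(two[1, ], no_truth, 6)
  split_b <- fa_per_24h(two[2, ], no_truth, 4)
  expect_equal(whole, (split_a * 6 + split_b * 4) / 10)

  # events overlapping a true seizure are not false alarms
  tr <- data.frame(onset_s = 5, offset_s = 20)
  expect_equal(fa_per_24h(two, tr, 24), 1)
})

test_that("the zero-FA frontier picks the most sensitive zero-alarm model", {
  toy <- data.frame(patient = c("p1", "p1"), model = c("A", "B"),
                    sensitivity = c(0.8, 0.9), fa_per_24h = c(0, 0.1))
  fr <- zero_fa_frontier(toy)
  expect_equal(fr$frontier$model, "A")
  expect_equal(fr$mean_sensitivity, 0.8)

  never <- data.frame(patient = "p2", model = c("A", "B"),
                      sensitivity = c(0.9, 0.95), fa_per_24h = c(1, 2))
  fr2 <- zero_fa_frontier(never)
  expect_false(fr2$frontier$attained)
  expect_true(is.na(fr2$frontier$sensitivity))
})
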