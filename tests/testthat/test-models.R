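# Model specs, pipelines, calibration, and the LOSO harness on compact
# synthetic feature matrices.

test_that("model specifications carry the protocol hyperparameters", {
  xg <- model_spec("xgboost")
  expect_equal(xg$hyperparameters$nrounds, 200L)
  expect_equal(xg$hyperparameters$eta, 0.1)
  expect_equal(xg$hyperparameters$max_depth, 6L)
  expect_equal(xg$hyperparameters$subsample, 0.8)
  expect_equal(xg$hyperparameters$colsample_bytree, 0.8)
  expect_equal(xg$hyperparameters$gamma, 0.1)
  expect_equal(xg$hyperparameters$min_child_weight, 5)
  expect_equal(xg$seed, 42L)

  et <- model_spec("extra_trees")
  expect_equal(et$hyperparameters$num_trees, 100L)
  expect_equal(et$hyperparameters$min_node_size, 5L)

  expect_error(model_spec("lightgbm"), "no R backend")
  expect_error(model_spec("catboost"), "no R backend")
  expect_error(model_spec("deep_net"), "arg")
})

test_that("scale_pos_weight follows the capped imbalance rule", {
  expect_equal(ictalarm:::xgb_scale_pos_weight(500, 1), 100)
  expect_equal(ictalarm:::xgb_scale_pos_weight(500, 25), 20)
  expect_equal(ictalarm:::xgb_scale_pos_weight(40, 10), 4)
  # and reaches the fitted booster's configuration
  set.seed(61)
  X <- matrix(rnorm(600 * 4), 600, 4)
  colnames(X) <- paste0("f", 1:4)
  y <- c(rep(1L, 3), rep(0L, 597))
  m <- fit_model(model_spec("xgboost", nrounds = 5L), X, y)
  cfgs <- xgboost::xgb.config(m$fit)
  if (is.character(cfgs)) cfgs <- jsonlite::fromJSON(cfgs)
  spw <- as.numeric(cfgs$learner$objective$reg_loss_param$scale_pos_weight)
  expect_equal(spw, 100)
})

test_that("fits are deterministic under a fixed seed", {
  fm <- toy_feature_matrix()
  X <- fm$values; y <- fm$labels
  for (nm in c("xgboost", "extra_trees", "random_forest", "logistic")) {
    sp <- model_spec(nm, seed = 42L)
    if (nm == "xgboost") sp$hyperparameters$nrounds <- 20L
    m1 <- fit_model(sp, X, y)
    m2 <- fit_model(sp, X, y)
    expect_identical(predict(m1, X), predict(m2, X), label = nm)
  }
})

test_that("every model separates the toy problem", {
  fm <- toy_feature_matrix()
  tr <- fm$groups != "t01"
  for (nm in c("xgboost", "extra_trees", "random_forest", "logistic")) {
    m <- fit_model(model_spec(nm), fm$values[tr, ], fm$labels[tr])
    auc <- ictalarm:::rank_auc(predict(m, fm$values[!tr, ]),
                               fm$labels[!tr])
    expect_gt(auc, 0.9)
  }
})

test_that("isotonic calibration is monotone and sharpens separated scores", {
  set.seed(62)
  scores <- c(runif(50, 0, 0.3), runif(50, 0.7, 1))
  labels <- rep(c(0L, 1L), each = 50)
  cal <- fit_calibrator(scores, labels)
  p <- predict(cal, sort(runif(200)))
  expect_true(all(diff(p) >= -1e-12))
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(predict(cal, scores[labels == 1]) > 0.99))
  expect_true(all(predict(cal, scores[labels == 0]) < 0.01))

  expect_warning(ident <- fit_calibrator(runif(10), rep(1L, 10)),
                 "single-class")
  expect_equal(predict(ident, c(0.2, 0.8)), c(0.2, 0.8))
})

test_that("calibration never worsens ECE on its own split", {
  set.seed(63)
  raw <- runif(400)
  labels <- rbinom(400, 1, raw^3)        # miscalibrated scores
  cal <- fit_calibrator(raw, labels)
  before <- calibration_quality(raw, labels)$ece
  after <- calibration_quality(predict(cal, raw), labels)$ece
  expect_lte(after, before + 1e-9)
})

test_that("the LOSO harness is leakage-safe and reproducible", {
  fm <- toy_feature_matrix(n_subj = 4L)
  spec <- model_spec("xgboost", nrounds = 30L)
  cfg <- loso_config(seed = 42L)
  res <- run_loso(fm, spec, cfg)
  expect_named(res$models, "xgboost")
  expect_equal(length(res$models$xgboost), 4L)
  aucs <- vapply(res$models$xgboost, function(f) f$metrics[["auc"]],
                 numeric(1))
  expect_true(all(aucs > 0.9))

  # fold results identical when the held-out subject's rows are removed
  # from the universe before training
  s <- "t02"
  direct <- ictalarm:::fit_fold(
    ictalarm:::subset_rows(fm, fm$groups != s),
    ictalarm:::subset_rows(fm, fm$groups == s), spec, cfg)
  expect_identical(direct$calibrated_probs,
                   res$models$xgboost[[s]]$calibrated_probs)
  expect_identical(direct$raw_scores, res$models$xgboost[[s]]$raw_scores)

  # end-to-end reproducibility
  res2 <- run_loso(fm, spec, cfg)
  expect_identical(lapply(res$models$xgboost, `[[`, "calibrated_probs"),
                   lapply(res2$models$xgboost, `[[`, "calibrated_probs"))

  # calibrated probabilities stay in [0, 1]
  for (f in res$models$xgboost) {
    expect_true(all(f$calibrated_probs >= 0 & f$calibrated_probs <= 1))
  }
})

test_that("shuffled labels drive the mean AUC to chance", {
  fm <- toy_feature_matrix(n_subj = 4L, n_per = 100L)
  set.seed(64)
  fm$labels <- sample(fm$labels)
  fm$meta$overlap_frac <- as.numeric(fm$labels)
  ok <- vapply(unique(fm$groups), function(s) {
    sum(fm$labels[fm$groups != s]) > 0 && sum(fm$labels[fm$groups == s]) > 0
  }, logical(1))
  res <- run_loso(fm, model_spec("xgboost", nrounds = 30L),
                  loso_config(seed = 7L))
  aucs <- vapply(res$models$xgboost, function(f) f$metrics[["auc"]],
                 numeric(1))
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.2)
})

test_that("LOSO refuses degenerate subject structures", {
  fm <- toy_feature_matrix(n_subj = 2L)
  one <- ictalarm:::subset_rows(fm, fm$groups == "t01")
  expect_error(run_loso(one, model_spec("xgboost")), "two subjects")
  fm$labels[fm$groups != "t01"] <- 0L
  expect_error(run_loso(fm, model_spec("xgboost")), "without positives")
})
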