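# Classifier suite, leave-one-subject-out harness, isotonic calibration.
#
# Every model is a pipeline: per-fold standardizer (mean/SD fit on the
# training rows) followed by the classifier with its fixed
# hyperparameters. Boosted models cap scale_pos_weight at 100.

#' Specification of one classifier
#'
#' Fixed hyperparameters: XGBoost 200 trees, learning rate 0.1,
#' max_depth 6, subsample 0.8, colsample_bytree 0.8, gamma 0.1,
#' min_child_weight 5, scale_pos_weight = min(neg/pos, 100); Extra Trees
#' and Random Forest 100 trees, sqrt feature sampling, minimum leaf size
#' 5, balanced class weights; the logistic baseline is an L2-penalized
#' ridge fit (C = 1.0 equivalence) with balanced class weights. The
#' `lightgbm` and `catboost` configurations have no available R backend
#' and raise an error naming the gap.
#'
#' @param name one of "xgboost", "extra_trees", "random_forest",
#'   "logistic" (also accepted but unavailable: "lightgbm", "catboost").
#' @param seed RNG seed used for fitting (default 42).
#' @param ... hyperparameter overrides.
#' @return a `model_spec`.
#' @export
model_spec <- function(name, seed = 42L, ...) {
  name <- match.arg(name, c("xgboost", "lightgbm", "catboost",
                            "extra_trees", "random_forest", "logistic"))
  if (name %in% c("lightgbm", "catboost")) {
    stop("no R backend for '", name, "' is available in this toolchain; ",
         "use xgboost, extra_trees, random_forest or logistic")
  }
  defaults <- switch(name,
    xgboost = list(nrounds = 200L, eta = 0.1, max_depth = 6L,
                   subsample = 0.8, colsample_bytree = 0.8, gamma = 0.1,
                   min_child_weight = 5, scale_pos_weight_cap = 100),
    extra_trees = list(num_trees = 100L, min_node_size = 5L,
                       mtry_rule = "sqrt"),
    random_forest = list(num_trees = 100L, min_node_size = 5L,
                         mtry_rule = "sqrt"),
    logistic = list(C = 1.0))
  over <- list(...)
  defaults[names(over)] <- over
  structure(list(name = name, seed = as.integer(seed),
                 hyperparameters = defaults),
            class = "model_spec")
}

# scale_pos_weight with the stability cap applied to boosted models.
xgb_scale_pos_weight <- function(n_neg, n_pos, cap = 100) {
  min(n_neg / max(n_pos, 1L), cap)
}

fit_standardizer <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}

apply_standardizer <- function(X, st) {
  sweep(sweep(X, 2, st$mean, "-"), 2, st$sd, "/")
}

#' Fit one classifier pipeline
#'
#' Standardizes the training matrix, fits the classifier named by the
#' spec, and returns a predictor. Deterministic given data, spec and the
#' spec's seed (single-threaded fits).
#'
#' @param spec a [model_spec()].
#' @param X numeric training matrix (rows = segments).
#' @param y binary labels.
#' @return a `seizure_model`; use [predict.seizure_model()] for
#'   positive-class probabilities.
#' @export
fit_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"), nrow(X) == length(y))
  y <- as.integer(y)
  st <- fit_standardizer(X)
  Xs <- apply_standardizer(X, st)
  hp <- spec$hyperparameters
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  fit <- switch(spec$name,
    xgboost = {
      spw <- xgb_scale_pos_weight(n_neg, n_pos, hp$scale_pos_weight_cap)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = hp$eta,
                      max_depth = hp$max_depth, subsample = hp$subsample,
                      colsample_bytree = hp$colsample_bytree,
                      gamma = hp$gamma, min_child_weight = hp$min_child_weight,
                      scale_pos_weight = spw, base_score = 0.5,
                      nthread = 1, seed = spec$seed),
        data = xgboost::xgb.DMatrix(Xs, label = y), nrounds = hp$nrounds,
        verbose = 0)
    },
    extra_trees = ,
    random_forest = {
      cw <- c("0" = length(y) / (2 * max(n_neg, 1L)),
              "1" = length(y) / (2 * max(n_pos, 1L)))
      ranger::ranger(x = as.data.frame(Xs), y = factor(y, levels = c(0, 1)),
                     num.trees = hp$num_trees,
                     mtry = floor(sqrt(ncol(Xs))),
                     min.node.size = hp$min_node_size,
                     splitrule = if (spec$name == "extra_trees")
                       "extratrees" else "gini",
                     num.random.splits = 1L,
                     probability = TRUE, seed = spec$seed,
                     num.threads = 1L, class.weights = cw,
                     respect.unordered.factors = FALSE, verbose = FALSE)
    },
    logistic = {
      w <- ifelse(y == 1L, length(y) / (2 * max(n_pos, 1L)),
                  length(y) / (2 * max(n_neg, 1L)))
      glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                     lambda = 1 / (hp$C * length(y)),
                     weights = w, standardize = FALSE)
    })
  structure(list(spec = spec, standardizer = st, fit = fit,
                 feature_names = colnames(X)),
            class = "seizure_model")
}

#' Positive-class probabilities from a fitted pipeline
#'
#' @param object a `seizure_model`.
#' @param newdata numeric matrix with the training columns.
#' @param type "prob" for probabilities, "margin" for the raw score on
#'   the link scale (xgboost/logistic) or the probability itself (trees).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.seizure_model <- function(object, newdata, type = c("prob", "margin"),
                                  ...) {
  type <- match.arg(type)
  Xs <- apply_standardizer(newdata[, object$feature_names, drop = FALSE],
                           object$standardizer)
  switch(object$spec$name,
    xgboost = stats::predict(object$fit, xgboost::xgb.DMatrix(Xs),
                             outputmargin = (type == "margin")),
    extra_trees = ,
    random_forest = stats::predict(object$fit, data = as.data.frame(Xs),
                                   num.threads = 1L)$predictions[, "1"],
    logistic = as.numeric(stats::predict(
      object$fit, Xs, type = if (type == "margin") "link" else "response")))
}

#' @export
print.seizure_model <- function(x, ...) {
  cat("<seizure_model>", x$spec$name, "on", length(x$feature_names),
      "features\n")
  invisible(x)
}

#' Fit an isotonic score-to-probability calibrator
#'
#' Non-decreasing least-squares fit of outcomes on raw scores (pooled
#' adjacent violators via [stats::isoreg()]); between knots the map is
#' linearly interpolated and clamped to [0, 1]. With a single-class
#' calibration split the identity map is returned with a warning.
#'
#' @param raw_scores classifier scores on the calibration split.
#' @param labels binary outcomes.
#' @return an `isotonic_calibrator`; apply with `predict()`.
#' @export
fit_calibrator <- function(raw_scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    warning("single-class calibration split; identity calibration")
    return(structure(list(identity = TRUE), class = "isotonic_calibrator"))
  }
  ord <- order(raw_scores)
  iso <- stats::isoreg(raw_scores[ord], labels[ord])
  ux <- unique(iso$x)
  grp <- factor(match(iso$x, ux), levels = seq_along(ux))
  uy <- as.numeric(tapply(iso$yf, grp, mean))
  structure(list(identity = FALSE, x = ux, y = pmin(pmax(uy, 0), 1)),
            class = "isotonic_calibrator")
}

#' @export
predict.isotonic_calibrator <- function(object, newdata, ...) {
  if (isTRUE(object$identity)) return(pmin(pmax(newdata, 0), 1))
  if (length(object$x) == 1L) {
    return(rep(object$y, length(newdata)))
  }
  stats::approx(object$x, object$y, xout = newdata, rule = 2,
                ties = "ordered")$y
}

# Deterministic stratified 80/20 split of training rows.
calibration_split <- function(y, frac = 0.2, seed = 42L) {
  idx_cal <- with_seed(seed, {
    unlist(lapply(split(seq_along(y), y), function(ix) {
      k <- max(1L, round(frac * length(ix)))
      sample(ix, k)
    }))
  })
  sort(idx_cal)
}

segment_metrics <- function(probs, labels, threshold = 0.5) {
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.finite(prec) && is.finite(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  c(accuracy = (tp + tn) / length(labels), precision = prec, recall = rec,
    f1 = f1, auc = rank_auc(probs, labels))
}

# Train on `train_fm`, calibrate on a stratified 20% split, score
# `test_fm` (and optionally `free_fm`). All fitting is confined to
# `train_fm`; the seed depends only on the held-out subject's identity,
# so fold results are invariant to the surrounding data universe.
fit_fold <- function(train_fm, test_fm, spec, cfg, free_fm = NULL) {
  seed_f <- derive_seed(cfg$seed, paste0("fold:", test_fm$groups[1]))
  cp <- fit_clean(train_fm)
  train_c <- apply_clean(train_fm, cp)
  colf <- collinearity_filter(train_c, threshold = cfg$collinearity_threshold,
                              sample_cap = cfg$collinearity_sample_cap,
                              seed = seed_f)
  train_c <- colf$fm
  keep_rows <- balance_classes(train_c$labels, max_ratio = cfg$balance_max_ratio,
                               seed = seed_f)
  train_b <- subset_rows(train_c, keep_rows)
  cal_idx <- calibration_split(train_b$labels, frac = cfg$calibration_frac,
                               seed = seed_f)
  fit_idx <- setdiff(seq_along(train_b$labels), cal_idx)
  spec$seed <- seed_f
  model <- fit_model(spec, train_b$values[fit_idx, , drop = FALSE],
                     train_b$labels[fit_idx])
  cal_scores <- predict(model, train_b$values[cal_idx, , drop = FALSE])
  calib <- fit_calibrator(cal_scores, train_b$labels[cal_idx])

  prep_test <- function(fm) {
    subset_features(apply_clean(fm, cp), colf$kept)
  }
  test_c <- prep_test(test_fm)
  raw <- predict(model, test_c$values)
  calp <- predict(calib, raw)
  free <- NULL
  if (!is.null(free_fm)) {
    free_c <- prep_test(free_fm)
    free_raw <- predict(model, free_c$values)
    free <- list(probs = predict(calib, free_raw),
                 labels = free_c$labels, meta = free_c$meta)
  }
  structure(list(held_out_subject = test_fm$groups[1],
                 raw_scores = raw,
                 calibrated_probs = calp,
                 labels = test_fm$labels,
                 meta = test_fm$meta,
                 kept_features = colf$kept,
                 model = model,
                 calibrator = calib,
                 metrics = segment_metrics(calp, test_fm$labels),
                 free = free),
            class = "fold_result")
}

#' Leave-one-subject-out training and scoring
#'
#' For each seizure-positive subject: all other positive subjects form
#' the training pool, which is cleaned, collinearity-filtered, balanced
#' (all seeded), fit, and isotonically calibrated on a stratified 20%
#' split; the held-out subject is then scored without refitting. No
#' test-subject information enters any fit. Optionally every fold's
#' model also scores a seizure-free pool for false-alarm assessment.
#'
#' @param fm `feature_matrix` of the seizure-positive subjects.
#' @param specs list of [model_spec()]s (or a single spec).
#' @param cfg a [loso_config()].
#' @param free_fm optional `feature_matrix` of seizure-free subjects.
#' @return a `loso_result`: list of per-model lists of `fold_result`s.
#' @export
run_loso <- function(fm, specs, cfg = loso_config(), free_fm = NULL) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  subjects <- unique(fm$groups)
  if (length(subjects) < 2L) stop("LOSO needs at least two subjects")
  with_pos <- vapply(subjects, function(s) {
    sum(fm$labels[fm$groups != s]) > 0
  }, logical(1))
  if (!all(with_pos)) {
    stop("training pool without positives for subject(s): ",
         paste(subjects[!with_pos], collapse = ", "))
  }
  models <- lapply(specs, function(spec) {
    folds <- lapply(subjects, function(s) {
      fit_fold(train_fm = subset_rows(fm, fm$groups != s),
               test_fm = subset_rows(fm, fm$groups == s),
               spec = spec, cfg = cfg, free_fm = free_fm)
    })
    names(folds) <- subjects
    folds
  })
  names(models) <- vapply(specs, function(s) s$name, "")
  structure(list(models = models, subjects = subjects, cfg = cfg),
            class = "loso_result")
}

#' Configuration for the LOSO harness
#'
#' @param seed base seed; per-fold seeds are derived from it and the
#'   held-out subject id.
#' @param collinearity_threshold absolute-correlation cut (default 0.95).
#' @param collinearity_sample_cap rows sampled for correlations.
#' @param balance_max_ratio negative:positive cap (default 20).
#' @param calibration_frac calibration-split fraction (default 0.2).
#' @return a `loso_config` list.
#' @export
loso_config <- function(seed = 42L, collinearity_threshold = 0.95,
                        collinearity_sample_cap = 20000L,
                        balance_max_ratio = 20, calibration_frac = 0.2) {
  structure(list(seed = as.integer(seed),
                 collinearity_threshold = collinearity_threshold,
                 collinearity_sample_cap = as.integer(collinearity_sample_cap),
                 balance_max_ratio = balance_max_ratio,
                 calibration_frac = calibration_frac),
            class = "loso_config")
}

#' @export
print.loso_result <- function(x, ...) {
  cat("<loso_result>", length(x$subjects), "folds x",
      length(x$models), "model(s)\n")
  print(summary(x))
  invisible(x)
}

#' @export
summary.loso_result <- function(object, ...) {
  rows <- lapply(names(object$models), function(m) {
    folds <- object$models[[m]]
    met <- t(vapply(folds, function(f) f$metrics, numeric(5)))
    data.frame(model = m, subject = names(folds),
               auc = met[, "auc"], recall = met[, "recall"],
               precision = met[, "precision"], f1 = met[, "f1"],
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.loso_result", "data.frame")
  out
}
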