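# TreeSHAP exactness, LIME surrogates, consistency, topography,
# ablation, stability.

test_that("global importance is the mean absolute attribution", {
  phi <- matrix(c(1, 3, -2, 0), 2, 2,
                dimnames = list(NULL, c("a", "b")))
  rk <- shap_global(phi)
  expect_equal(rk$feature, c("a", "b"))
  expect_equal(rk$score, c(2, 1))

  zero <- matrix(0, 4, 2, dimnames = list(NULL, c("a", "b")))
  expect_true(all(shap_global(zero)$score == 0))
})

test_that("TreeSHAP matches brute-force Shapley on hand-built trees", {
  # two stumps-of-stumps with no feature repeated along any path
  tree1 <- list(left = c(1L, 3L, 5L, -1L, -1L, -1L, -1L),
                right = c(2L, 4L, 6L, -1L, -1L, -1L, -1L),
                def = c(1L, 3L, 5L, -1L, -1L, -1L, -1L),
                feature = c(0L, 1L, 2L, -1L, -1L, -1L, -1L),
                thresh = c(0, 0.5, -0.5, 0, 0, 0, 0),
                value = c(0, 0, 0, 1.5, -0.5, 2.0, 0.25),
                cover = c(100, 60, 40, 35, 25, 10, 30))
  tree2 <- list(left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
                def = c(1L, -1L, -1L), feature = c(2L, -1L, -1L),
                thresh = c(1, 0, 0), value = c(0, -1, 1),
                cover = c(100, 70, 30))
  trees <- list(tree1, tree2)

  exp_val <- function(T, node, x, S) {
    if (T$feature[node] < 0) return(T$value[node])
    f <- T$feature[node] + 1L
    l <- T$left[node] + 1L; r <- T$right[node] + 1L
    if (f %in% S) {
      if (x[f] < T$thresh[node]) exp_val(T, l, x, S)
      else exp_val(T, r, x, S)
    } else {
      (T$cover[l] * exp_val(T, l, x, S) +
         T$cover[r] * exp_val(T, r, x, S)) / T$cover[node]
    }
  }
  shapley_brute <- function(trees, x, M) {
    v <- function(S) sum(vapply(trees, exp_val, numeric(1), node = 1L,
                                x = x, S = S))
    vapply(seq_len(M), function(j) {
      others <- setdiff(seq_len(M), j)
      tot <- 0
      for (mask in 0:(2^length(others) - 1)) {
        S <- others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0]
        w <- factorial(length(S)) * factorial(M - length(S) - 1) /
          factorial(M)
        tot <- tot + w * (v(c(S, j)) - v(S))
      }
      tot
    }, numeric(1))
  }

  set.seed(81)
  X <- matrix(rnorm(12), 4, 3)
  got <- ictalarm:::treeshap_cpp(X, trees)
  for (i in 1:4) {
    want <- shapley_brute(trees, X[i, ], 3L)
    expect_equal(got[i, 1:3], want, tolerance = 1e-10)
    # additivity: base + sum phi = full-coverage prediction
    full <- sum(vapply(trees, exp_val, numeric(1), node = 1L,
                       x = X[i, ], S = 1:3))
    expect_equal(got[i, 4] + sum(got[i, 1:3]), full, tolerance = 1e-12)
  }
})

test_that("TreeSHAP on a fitted booster satisfies additivity and matches xgboost", {
  fm <- toy_feature_matrix(n_subj = 2L, n_per = 150L)
  m <- fit_model(model_spec("xgboost", nrounds = 50L), fm$values, fm$labels)
  sv <- shap_values(m, fm$values)
  expect_lt(max(abs(sv$base_value + rowSums(sv$values) - sv$margin)), 1e-9)
  # float32 library implementation agrees to its precision
  Xs <- ictalarm:::apply_standardizer(fm$values, m$standardizer)
  pc <- predict(m$fit, xgboost::xgb.DMatrix(Xs), predcontrib = TRUE)
  expect_lt(max(abs(pc[, colnames(sv$values)] - sv$values)), 1e-4)
  # and the double margin matches the booster's margin to float precision
  marg <- predict(m$fit, xgboost::xgb.DMatrix(Xs), outputmargin = TRUE)
  expect_lt(max(abs(marg - sv$margin)), 1e-4)
})

test_that("LIME recovers the active feature and is deterministic", {
  set.seed(82)
  n <- 400; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", 1:p)
  y <- as.integer(X[, 3] > 0)
  m <- fit_model(model_spec("xgboost", nrounds = 40L), X, y)
  bg <- list(mean = colMeans(X), sd = apply(X, 2, sd))
  x0 <- X[1, ]
  r1 <- lime_local(m, x0, bg, k = 3L, seed = 9L)
  r2 <- lime_local(m, x0, bg, k = 3L, seed = 9L)
  expect_equal(r1$feature[1], "f3")
  expect_identical(r1, r2)
  r3 <- lime_local(m, x0, bg, k = 3L, seed = 10L)
  expect_false(identical(r1$score, r3$score))
})

test_that("LIME weights track a linear model's standardized coefficients", {
  set.seed(83)
  n <- 500; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  X[, 2] <- X[, 2] * 3                     # unequal scales
  colnames(X) <- paste0("f", 1:p)
  beta_true <- c(1.5, -0.8, 0.6, 0, 0)
  pr <- plogis(X %*% beta_true)
  y <- rbinom(n, 1, pr)
  m <- fit_model(model_spec("logistic"), X, y)
  bg <- list(mean = colMeans(X), sd = apply(X, 2, sd))
  r <- lime_local(m, X[7, ], bg, k = p, n_perturb = 1000L, seed = 3L)
  w <- attr(r, "weights")[colnames(X)]
  expect_gt(stats::cor(w, beta_true * apply(X, 2, sd)), 0.9)
})

test_that("consistency and Jaccard behave on overlap patterns", {
  shared <- paste0("s", 1:3)
  a <- c(shared, paste0("a", 1:7))
  b <- c(shared, paste0("b", 1:7))
  got <- explanation_consistency(a, b)
  expect_equal(got$jaccard, 3 / 17)
  expect_equal(got$consistency, 3 / 10)

  same <- explanation_consistency(a, a)
  expect_equal(same$consistency, 1)
  expect_equal(same$jaccard, 1)

  dis <- explanation_consistency(paste0("x", 1:5), paste0("y", 1:5))
  expect_equal(dis$consistency, 0)
  expect_equal(dis$jaccard, 0)

  expect_error(explanation_consistency(a, character()), "empty")

  # Jaccard symmetric; the printed-ratio consistency is not
  asym_a <- paste0("s", 1:3)
  asym_b <- c(asym_a, paste0("b", 1:7))
  ab <- explanation_consistency(asym_a, asym_b)
  ba <- explanation_consistency(asym_b, asym_a)
  expect_equal(ab$jaccard, ba$jaccard)
  expect_false(isTRUE(all.equal(ab$consistency, ba$consistency)))
})

test_that("channel topography aggregates and normalizes per channel", {
  sc <- c("A__f1" = 0, "A__f2" = 0, "B__f1" = 2, "B__f2" = 3,
          "global_max_rms" = 99)
  topo <- channel_topography(sc)
  expect_equal(unname(topo[c("A", "B")]), c(0, 1))
  expect_false("global_max_rms" %in% names(topo))

  flat <- channel_topography(c("A__f" = 1, "B__f" = 1, "C__f" = 1))
  expect_true(all(flat == 1))

  set.seed(84)
  rnd <- channel_topography(stats::setNames(runif(9),
                                            paste0(rep(c("A", "B", "C"), 3),
                                                   "__f", 1:9)))
  expect_true(all(rnd >= 0 & rnd <= 1))
})

test_that("ablation with all features reproduces the full model exactly", {
  fm <- toy_feature_matrix(n_subj = 3L, n_per = 60L, p = 6L)
  spec <- model_spec("xgboost", nrounds = 20L)
  cfg <- loso_config(seed = 42L)
  full <- run_loso(fm, spec, cfg)
  full_auc <- vapply(full$models[[1]], function(f) f$metrics[["auc"]],
                     numeric(1))
  ranking <- new_ranked_features(
    stats::setNames(seq(ncol(fm$values), 1), fm$feature_names))
  tab <- feature_ablation(fm, ranking, ks = ncol(fm$values), spec, cfg)
  expect_equal(stats::setNames(tab$auc, tab$patient), full_auc)
  expect_equal(nrow(tab), length(unique(fm$groups)))

  expect_warning(capped <- feature_ablation(fm, ranking,
                                            ks = ncol(fm$values) + 5,
                                            spec, cfg),
                 "capped")
  expect_equal(stats::setNames(capped$auc, capped$patient), full_auc)
})

test_that("the stability table counts appearances and patient coverage", {
  rk <- function(...) c(...)
  rankings <- list(
    m1 = list(p1 = rk("a", "b"), p2 = rk("a", "c")),
    m2 = list(p1 = rk("a", "d"), p2 = rk("b", "c")))
  tab <- stability_table(rankings, k = 2L)
  expect_equal(tab$count[tab$feature == "a"], 3L)
  expect_equal(tab$coverage_pct[tab$feature == "a"], 100)
  expect_equal(tab$coverage_pct[tab$feature == "d"], 50)
  expect_false("zzz" %in% tab$feature)
  # counting bound: total appearances <= k x folds x models
  expect_lte(sum(tab$count), 2 * 2 * 2)
})
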