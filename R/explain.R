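# Attribution analysis: exact TreeSHAP global importance, LIME-style
# local surrogates, SHAP-LIME consistency, channel topography, top-k
# ablation, and cross-fold stability tables.

#' Ordered feature ranking
#'
#' @param scores named numeric vector of importances.
#' @return a `ranked_features` data.frame (`feature`, `score`), ordered
#'   by decreasing score with ties broken by name.
#' @export
new_ranked_features <- function(scores) {
  stopifnot(!is.null(names(scores)))
  ord <- order(-scores, names(scores))
  structure(data.frame(feature = names(scores)[ord],
                       score = unname(scores[ord]),
                       stringsAsFactors = FALSE),
            class = c("ranked_features", "data.frame"))
}

top_features <- function(ranking, k) {
  if (is.character(ranking)) return(utils::head(ranking, k))
  utils::head(ranking$feature, k)
}

# Parse an xgboost booster into flat per-tree arrays for the C++
# TreeSHAP kernel (0-based child indices, feature -1 at leaves).
xgb_tree_structure <- function(booster, feature_names) {
  txt <- paste(xgboost::xgb.dump(booster, dump_format = "json",
                                 with_stats = TRUE), collapse = "")
  trees <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  lapply(trees, function(root) {
    nodes <- list()
    collect <- function(nd) {
      nodes[[length(nodes) + 1L]] <<- nd
      for (ch in nd$children %||% list()) collect(ch)
    }
    collect(root)
    ids <- vapply(nodes, function(n) n$nodeid, numeric(1))
    idx_of <- function(id) match(id, ids) - 1L
    is_leaf <- vapply(nodes, function(n) !is.null(n$leaf), logical(1))
    list(
      left = vapply(nodes, function(n)
        if (is.null(n$yes)) -1L else idx_of(n$yes), integer(1)),
      right = vapply(nodes, function(n)
        if (is.null(n$no)) -1L else idx_of(n$no), integer(1)),
      def = vapply(nodes, function(n)
        if (is.null(n$missing)) -1L else idx_of(n$missing), integer(1)),
      feature = vapply(nodes, function(n) {
        if (!is.null(n$leaf)) return(-1L)
        j <- match(n$split, feature_names)
        if (is.na(j)) stop("unknown split feature: ", n$split)
        j - 1L
      }, integer(1)),
      thresh = vapply(nodes, function(n)
        if (is.null(n$split_condition)) 0 else n$split_condition, numeric(1)),
      value = vapply(nodes, function(n)
        if (is.null(n$leaf)) 0 else n$leaf, numeric(1)),
      cover = vapply(nodes, function(n) n$cover, numeric(1)))
  })
}

#' Exact TreeSHAP attributions for an xgboost pipeline
#'
#' Double-precision path-dependent TreeSHAP on the booster's tree
#' structure. Attributions are on the margin (log-odds) scale; the base
#' value is the cover-weighted expected margin. Because the margin used
#' for the additivity identity is computed from the same trees in double
#' precision, `base + rowSums(phi)` matches it to machine precision.
#'
#' @param model a `seizure_model` with an xgboost fit (or an
#'   `xgb.Booster` plus explicit `feature_names`).
#' @param X numeric matrix of samples (unstandardized for a
#'   `seizure_model`; the pipeline's standardizer is applied).
#' @param feature_names required when `model` is a raw booster.
#' @return an `attribution_set`: list with `method = "shap"`, `values`
#'   (`[n x p]` matrix), `base_value`, `feature_names`, and `margin`
#'   (double-precision margin predictions).
#' @export
shap_values <- function(model, X, feature_names = NULL) {
  if (inherits(model, "seizure_model")) {
    if (model$spec$name != "xgboost") {
      stop("exact tree attributions require an xgboost model")
    }
    feature_names <- model$feature_names
    Xs <- apply_standardizer(X[, feature_names, drop = FALSE],
                             model$standardizer)
    booster <- model$fit
  } else {
    stopifnot(!is.null(feature_names))
    Xs <- X
    booster <- model
  }
  trees <- xgb_tree_structure(booster, feature_names)
  out <- treeshap_cpp(as.matrix(Xs), trees)
  p <- length(feature_names)
  phi <- out[, seq_len(p), drop = FALSE]
  colnames(phi) <- feature_names
  base <- out[1, p + 1L]
  structure(list(method = "shap", values = phi, base_value = base,
                 feature_names = feature_names,
                 margin = tree_margin_cpp(as.matrix(Xs), trees, 0)),
            class = "attribution_set")
}

#' Global SHAP importance
#'
#' Mean absolute attribution per feature, I_j = (1/N) sum_i |phi_ij|,
#' ranked in decreasing order (ties by name).
#'
#' @param phi attribution matrix (`[n x p]`), an `attribution_set`, or a
#'   `seizure_model` together with `X`.
#' @param X samples, required when `phi` is a model.
#' @return a `ranked_features` data.frame.
#' @export
shap_global <- function(phi, X = NULL) {
  if (inherits(phi, "seizure_model")) phi <- shap_values(phi, X)
  if (inherits(phi, "attribution_set")) phi <- phi$values
  stopifnot(is.matrix(phi), !is.null(colnames(phi)))
  new_ranked_features(colMeans(abs(phi)))
}

#' LIME-style local surrogate explanation
#'
#' Gaussian perturbations around the sample (seeded), proximity-weighted
#' ridge regression of the model's probabilities on the standardized
#' perturbation offsets, and the top-k coefficients by absolute weight.
#' Zero-variance background features are not perturbed.
#'
#' @param model object with a `predict(model, X)` probability method.
#' @param x single sample (named numeric vector or 1-row matrix).
#' @param background list with `mean` and `sd` per feature (training-fold
#'   statistics).
#' @param n_perturb number of perturbed samples.
#' @param kernel_width proximity kernel width; default `0.75 * sqrt(p)`.
#' @param k size of the returned feature set.
#' @param ridge_lambda ridge penalty.
#' @param seed RNG seed.
#' @return a `ranked_features` of the top-k features (scores = |weight|),
#'   with the signed weights in attribute `"weights"`.
#' @export
lime_local <- function(model, x, background, n_perturb = 500L,
                       kernel_width = NULL, k = 10L, ridge_lambda = 0.01,
                       seed = 42L) {
  x <- drop(as.matrix(x))
  nm <- names(x) %||% names(background$mean)
  p <- length(x)
  sdv <- background$sd
  sdv[!is.finite(sdv)] <- 0
  kernel_width <- kernel_width %||% (0.75 * sqrt(p))
  Z <- with_seed(seed, {
    offs <- matrix(stats::rnorm(n_perturb * p), n_perturb, p)
    sweep(offs, 2, sdv, "*")
  })
  Xp <- sweep(Z, 2, x, "+")
  colnames(Xp) <- nm
  yp <- predict(model, Xp)
  Zs <- sweep(Z, 2, ifelse(sdv > 0, sdv, 1), "/")  # standardized offsets
  d2 <- rowMeans(Zs^2)
  w <- exp(-d2 / kernel_width^2)
  # weighted ridge in closed form
  sw <- sqrt(w)
  Zw <- Zs * sw
  yw <- (yp - stats::weighted.mean(yp, w)) * sw
  A <- crossprod(Zw) + diag(ridge_lambda, p)
  beta <- drop(solve(A, crossprod(Zw, yw)))
  names(beta) <- nm
  beta[sdv == 0] <- 0
  rk <- new_ranked_features(abs(beta))
  out <- utils::head(rk, k)
  class(out) <- class(rk)
  attr(out, "weights") <- beta
  out
}

#' Agreement between SHAP and LIME feature sets
#'
#' Two statistics over the top-k feature names: the asymmetric overlap
#' |F_SHAP intersect F_LIME| / |F_LIME|, and the Jaccard index
#' |intersect| / |union| (the default headline statistic).
#'
#' @param f_shap,f_lime `ranked_features` or character vectors.
#' @param k optional truncation applied to both sets.
#' @return list with `consistency` and `jaccard`.
#' @export
explanation_consistency <- function(f_shap, f_lime, k = NULL) {
  a <- if (is.character(f_shap)) f_shap else f_shap$feature
  b <- if (is.character(f_lime)) f_lime else f_lime$feature
  if (!is.null(k)) { a <- utils::head(a, k); b <- utils::head(b, k) }
  if (!length(b)) stop("empty LIME feature set")
  inter <- length(intersect(a, b))
  list(consistency = inter / length(b),
       jaccard = inter / length(union(a, b)))
}

#' Channel-level aggregation of feature importance
#'
#' Sums importances per channel over features named `{CHANNEL}__{feat}`
#' (global summaries are excluded) and min-max normalizes to [0, 1];
#' a constant score vector maps to all ones.
#'
#' @param ranking a `ranked_features` (or named score vector).
#' @return named numeric vector of per-channel scores in [0, 1].
#' @export
channel_topography <- function(ranking) {
  if (is.data.frame(ranking)) {
    scores <- stats::setNames(ranking$score, ranking$feature)
  } else scores <- ranking
  chan <- sub("__.*$", "", names(scores))
  has_ch <- grepl("__", names(scores), fixed = TRUE)
  tab <- tapply(scores[has_ch], chan[has_ch], sum)
  agg <- stats::setNames(as.numeric(tab), names(tab))
  rng <- range(agg)
  if (diff(rng) == 0) {
    return(stats::setNames(rep(1, length(agg)), names(agg)))
  }
  (agg - rng[1]) / diff(rng)
}

#' Top-k feature ablation over the LOSO protocol
#'
#' Re-runs the LOSO harness restricted to the top-k features of a
#' ranking, for each k, recording the per-fold segment AUC. `k` larger
#' than the available feature count is capped with a warning; `k` equal
#' to the full count reproduces the full model exactly.
#'
#' @param fm `feature_matrix` of the positive subjects.
#' @param ranking a `ranked_features` (e.g. from [shap_global()]).
#' @param ks subset sizes.
#' @param spec a [model_spec()].
#' @param cfg a [loso_config()].
#' @return data.frame with `k`, `patient`, `auc`.
#' @export
feature_ablation <- function(fm, ranking, ks = c(5, 10, 15, 20, 25, 30),
                             spec = model_spec("xgboost"),
                             cfg = loso_config()) {
  avail <- intersect(if (is.character(ranking)) ranking else ranking$feature,
                     fm$feature_names)
  out <- list()
  for (k in ks) {
    kk <- k
    if (kk > length(avail)) {
      warning("k = ", k, " exceeds available features; capped at ",
              length(avail))
      kk <- length(avail)
    }
    sub <- subset_features(fm, utils::head(avail, kk))
    res <- run_loso(sub, spec, cfg)
    aucs <- vapply(res$models[[1]], function(f) f$metrics[["auc"]], numeric(1))
    out[[as.character(k)]] <- data.frame(k = k,
                                         patient = names(aucs),
                                         auc = unname(aucs))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-fold feature stability table
#'
#' Counts, for each feature, its appearances in the top-k of per-(fold,
#' model) rankings, and the patient coverage: the percentage of subjects
#' in whose fold the feature reaches the top-k for at least one model.
#'
#' @param rankings nested list `rankings[[model]][[subject]]`, each a
#'   `ranked_features` or character vector.
#' @param k top-list size (default 20).
#' @return data.frame `feature`, `count`, `coverage_pct`, ordered by
#'   decreasing count; features never in a top-k are absent.
#' @export
stability_table <- function(rankings, k = 20L) {
  subjects <- unique(unlist(lapply(rankings, names)))
  stopifnot(length(subjects) >= 2L)
  counts <- list()
  covered <- list()
  for (m in names(rankings)) {
    for (s in names(rankings[[m]])) {
      feats <- top_features(rankings[[m]][[s]], k)
      for (f in feats) {
        counts[[f]] <- (counts[[f]] %||% 0L) + 1L
        covered[[f]] <- union(covered[[f]] %||% character(), s)
      }
    }
  }
  if (!length(counts)) {
    return(data.frame(feature = character(), count = integer(),
                      coverage_pct = numeric()))
  }
  out <- data.frame(feature = names(counts),
                    count = unlist(counts, use.names = FALSE),
                    coverage_pct = vapply(names(counts), function(f) {
                      100 * length(covered[[f]]) / length(subjects)
                    }, numeric(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
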