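# Feature-matrix finalization: cleaning, collinearity pruning, class
# balancing, and a two-component PCA sanity check. The fit/apply split
# lets every step be fit on a training fold and applied unchanged to the
# held-out subject.

#' Fit cleaning parameters on a feature matrix
#'
#' Per column: the median of finite entries (imputation value; 0 for
#' all-non-finite columns, with a warning), the mean/SD defining the
#' |z| > 5 outlier trigger, and the 0.1/99.9 percentile clip bounds.
#'
#' @param fm a `feature_matrix`.
#' @return a `clean_params` list.
#' @export
fit_clean <- function(fm) {
  X <- fm$values
  p <- ncol(X)
  med <- numeric(p); mu <- numeric(p); sdv <- numeric(p)
  qlo <- numeric(p); qhi <- numeric(p)
  all_bad <- logical(p)
  for (j in seq_len(p)) {
    v <- X[, j]
    fin <- v[is.finite(v)]
    if (!length(fin)) {
      all_bad[j] <- TRUE
      med[j] <- 0; mu[j] <- 0; sdv[j] <- 0; qlo[j] <- 0; qhi[j] <- 0
      next
    }
    med[j] <- stats::median(fin)
    v[!is.finite(v)] <- med[j]
    mu[j] <- mean(v); sdv[j] <- stats::sd(v)
    q <- stats::quantile(v, c(0.001, 0.999), names = FALSE, type = 7)
    qlo[j] <- q[1]; qhi[j] <- q[2]
  }
  if (any(all_bad)) {
    warning(sum(all_bad), " all-non-finite column(s) zero-filled: ",
            paste(utils::head(fm$feature_names[all_bad], 5), collapse = ", "))
  }
  structure(list(median = med, mean = mu, sd = sdv,
                 qlo = qlo, qhi = qhi,
                 feature_names = fm$feature_names),
            class = "clean_params")
}

#' Apply cleaning parameters
#'
#' Non-finite entries become the (training) column median; entries more
#' than 5 training SDs from the training mean are winsorized two-sided to
#' the training 0.1/99.9 percentiles. Columns expected by `params` but
#' absent from `fm` are zero-filled, preserving dimensional consistency.
#'
#' @param fm a `feature_matrix`.
#' @param params a `clean_params` from [fit_clean()].
#' @return cleaned `feature_matrix` with columns in `params` order.
#' @export
apply_clean <- function(fm, params) {
  stopifnot(inherits(params, "clean_params"))
  missing_cols <- setdiff(params$feature_names, fm$feature_names)
  X <- matrix(0, nrow(fm$values), length(params$feature_names),
              dimnames = list(NULL, params$feature_names))
  present <- intersect(params$feature_names, fm$feature_names)
  X[, present] <- fm$values[, present, drop = FALSE]
  if (length(missing_cols)) {
    warning(length(missing_cols), " expected feature column(s) zero-filled")
  }
  for (j in seq_along(params$feature_names)) {
    v <- X[, j]
    v[!is.finite(v)] <- params$median[j]
    if (params$sd[j] > 0) {
      z <- (v - params$mean[j]) / params$sd[j]
      v[z > 5] <- pmin(v[z > 5], params$qhi[j])
      v[z < -5] <- pmax(v[z < -5], params$qlo[j])
    }
    X[, j] <- v
  }
  new_feature_matrix(X, fm$labels, fm$groups, fm$meta)
}

#' Clean a feature matrix (fit + apply on the same data)
#'
#' @param fm a `feature_matrix`.
#' @return cleaned `feature_matrix`.
#' @export
clean_matrix <- function(fm) apply_clean(fm, fit_clean(fm))

#' Greedy collinearity filter
#'
#' Pearson correlations are computed on at most `sample_cap` randomly
#' sampled rows (seeded); scanning columns in canonical order, a column
#' is dropped when |r| >= `threshold` with any earlier kept column, so
#' the later member of each offending pair is removed. Zero-variance
#' columns have undefined r, treated as 0 (kept).
#'
#' @param fm a `feature_matrix` with >= 2 rows.
#' @param threshold absolute-correlation threshold.
#' @param sample_cap maximum rows used for the correlation estimate.
#' @param seed RNG seed for the row sample.
#' @return list with `fm` (filtered matrix) and `kept` (column names).
#' @export
collinearity_filter <- function(fm, threshold = 0.95, sample_cap = 20000L,
                                seed = 42L) {
  n <- nrow(fm$values)
  stopifnot(n >= 2L)
  idx <- if (n > sample_cap) {
    with_seed(seed, sample.int(n, sample_cap))
  } else seq_len(n)
  X <- fm$values[idx, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  r <- suppressWarnings(stats::cor(X))
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  p <- ncol(X)
  kept <- logical(p)
  for (j in seq_len(p)) {
    if (sds[j] == 0) { kept[j] <- TRUE; next }     # r undefined -> keep
    prior <- which(kept[seq_len(j - 1L)])
    kept[j] <- !length(prior) || all(abs(r[j, prior]) < threshold)
  }
  keep_names <- fm$feature_names[kept]
  list(fm = subset_features(fm, keep_names), kept = keep_names)
}

#' Undersample the majority class to a maximum ratio
#'
#' All positive rows are kept; negatives are uniformly subsampled
#' (seeded) so that #neg <= `max_ratio` x #pos.
#'
#' @param labels binary vector for the training fold.
#' @param max_ratio maximum negative:positive ratio.
#' @param seed RNG seed.
#' @return sorted integer indices of kept rows.
#' @export
balance_classes <- function(labels, max_ratio = 20, seed = 42L) {
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (!length(pos)) stop("no positive samples in training fold")
  cap <- floor(max_ratio * length(pos))
  if (length(neg) > cap) {
    neg <- with_seed(seed, sort(sample(neg, cap)))
  }
  sort(c(pos, neg))
}

#' Two-component PCA check
#'
#' Leading two explained-variance ratios of the standardized features on
#' a random subsample of at most `n_rows` rows. Diagnostic only.
#'
#' @param fm a `feature_matrix`.
#' @param n_rows subsample cap.
#' @param seed RNG seed for the subsample.
#' @return numeric length-2 vector of explained-variance fractions.
#' @export
pca_check <- function(fm, n_rows = 50000L, seed = 42L) {
  n <- nrow(fm$values)
  idx <- if (n > n_rows) with_seed(seed, sample.int(n, n_rows)) else seq_len(n)
  X <- fm$values[idx, , drop = FALSE]
  stopifnot(nrow(X) >= 2L)
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  (ev / sum(ev))[1:2]
}
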