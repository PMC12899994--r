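# Inferential and calibration statistics: one-sided equivalence test of
# FA/24h against the clinical 0.5/day limit, bootstrap CIs, paired
# nonparametric tests, ECE/Brier calibration quality, and a permutation
# null for attribution-ranking consistency.

#' One-sided t-test of FA/24 h against a clinical limit
#'
#' Tests H0: mean FA/24 h >= `limit` against the lower-tailed
#' alternative; t = (mean - limit)/(s/sqrt(n)), p the lower-tail
#' probability under t with n-1 df. When the sample is degenerate
#' (s = 0) the limit rule applies: p = 0 if the mean is below the limit,
#' 1 otherwise.
#'
#' @param fa_values per-fold FA/24 h values (n >= 2).
#' @param limit clinical false-alarm limit (default 0.5/day).
#' @return list with `t`, `p`, `mean`, `sd`, `n`.
#' @export
equivalence_fa_test <- function(fa_values, limit = 0.5) {
  n <- length(fa_values)
  if (n < 2L) stop("equivalence test needs n >= 2")
  m <- mean(fa_values)
  s <- stats::sd(fa_values)
  if (s == 0) {
    p <- if (m < limit) 0 else 1
    return(list(t = NA_real_, p = p, mean = m, sd = s, n = n))
  }
  t <- (m - limit) / (s / sqrt(n))
  list(t = t, p = stats::pt(t, df = n - 1), mean = m, sd = s, n = n)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param values numeric sample (n >= 1).
#' @param B number of resamples (default 5000).
#' @param level confidence level.
#' @param seed RNG seed.
#' @return numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(values, B = 5000L, level = 0.95, seed = 42L) {
  stopifnot(length(values) >= 1L)
  means <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      mean(sample(values, length(values), replace = TRUE))
    }, numeric(1))
  })
  a <- (1 - level) / 2
  unname(stats::quantile(means, c(a, 1 - a), type = 7))
}

#' Paired and unpaired nonparametric comparisons
#'
#' Wilcoxon signed-rank (paired; zero differences dropped, exact
#' two-sided p for small tie-free samples via the signed-rank
#' distribution, corrected normal approximation otherwise) and
#' Mann-Whitney U (unpaired). All-zero differences leave the Wilcoxon
#' undefined, flagged rather than zeroed.
#'
#' @param a,b numeric vectors (equal length for the paired test).
#' @return list with `wilcoxon_stat`, `wilcoxon_p`, `mann_whitney_p`,
#'   `n_nonzero`, `wilcoxon_defined`.
#' @export
paired_tests <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  nz <- d != 0
  mw <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))$p.value
  if (!any(nz)) {
    return(list(wilcoxon_stat = NA_real_, wilcoxon_p = NA_real_,
                mann_whitney_p = mw, n_nonzero = 0L,
                wilcoxon_defined = FALSE))
  }
  wt <- suppressWarnings(stats::wilcox.test(a[nz], b[nz], paired = TRUE,
                                            exact = TRUE))
  list(wilcoxon_stat = unname(wt$statistic), wilcoxon_p = wt$p.value,
       mann_whitney_p = mw, n_nonzero = sum(nz), wilcoxon_defined = TRUE)
}

#' Calibration quality: ECE, Brier score, reliability curve
#'
#' Equal-width bins over [0, 1] (decile binning by default); ECE is the
#' bin-weighted absolute gap between mean predicted probability and
#' empirical positive fraction; Brier is the mean squared error. Empty
#' bins are skipped.
#'
#' @param probs predicted probabilities in [0, 1].
#' @param labels binary outcomes.
#' @param bins number of equal-width bins (default 10).
#' @return list with `ece`, `brier`, `curve` (data.frame `bin`,
#'   `mean_prob`, `frac_pos`, `n`).
#' @export
calibration_quality <- function(probs, labels, bins = 10L) {
  stopifnot(length(probs) == length(labels),
            all(probs >= 0 & probs <= 1))
  labels <- as.integer(labels)
  cut_id <- pmin(pmax(floor(probs * bins) + 1L, 1L), bins)
  ece <- 0
  curve <- list()
  n <- length(probs)
  for (b in seq_len(bins)) {
    ix <- which(cut_id == b)
    if (!length(ix)) next
    conf <- mean(probs[ix]); acc <- mean(labels[ix])
    ece <- ece + length(ix) / n * abs(acc - conf)
    curve[[length(curve) + 1L]] <- data.frame(bin = b, mean_prob = conf,
                                              frac_pos = acc,
                                              n = length(ix))
  }
  list(ece = ece, brier = mean((probs - labels)^2),
       curve = do.call(rbind, curve))
}

mean_pairwise_jaccard <- function(sets) {
  m <- length(sets)
  if (m < 2L) return(NA_real_)
  tot <- 0; np <- 0
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      tot <- tot + length(intersect(sets[[i]], sets[[j]])) /
        length(union(sets[[i]], sets[[j]]))
      np <- np + 1
    }
  }
  tot / np
}

#' Permutation null for ranking consistency
#'
#' Observed statistic: mean pairwise Jaccard of the top-k feature sets
#' across folds. Null: feature identities are permuted independently per
#' fold within the feature universe; p = (1 + #{null >= observed}) /
#' (n_perm + 1).
#'
#' @param rankings list of `ranked_features` or character vectors (one
#'   per fold).
#' @param universe feature universe to permute within; default the union
#'   of all ranked features.
#' @param k top-list size; default the length of the shortest ranking.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return list with `observed`, `p`, `null_mean`.
#' @export
permutation_consistency_null <- function(rankings, universe = NULL, k = NULL,
                                         n_perm = 1000L, seed = 42L) {
  stopifnot(length(rankings) >= 2L)
  feats <- lapply(rankings, function(r) {
    if (is.character(r)) r else r$feature
  })
  universe <- universe %||% unique(unlist(feats))
  k <- k %||% min(lengths(feats))
  sets <- lapply(feats, utils::head, k)
  obs <- mean_pairwise_jaccard(sets)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm_sets <- lapply(sets, function(s) sample(universe, length(s)))
      mean_pairwise_jaccard(perm_sets)
    }, numeric(1))
  })
  list(observed = obs, p = (1 + sum(null >= obs)) / (n_perm + 1),
       null_mean = mean(null))
}
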