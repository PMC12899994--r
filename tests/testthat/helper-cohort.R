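# Shared fixtures, built once per test run and memoized.
#
# `study_*` accessors expose the default synthetic study conditions
# (6 seizure-positive + 3 seizure-free subjects, 600 s sessions, seed
# 42) used by the end-to-end checks; `toy_feature_matrix` provides a
# fast Gaussian-blob stand-in for model-level unit tests.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

study_params <- function() synth_params(seed = 42L)

study_dir <- function() {
  memo("study_dir", {
    dir <- file.path(tempdir(), "ictalarm-study-cohort")
    generate_cohort(study_params(), dir)
    dir
  })
}

study_annotations <- function() {
  parse_annotations(file.path(study_dir(), "annotations.csv"))
}

study_manifest <- function() {
  jsonlite::read_json(file.path(study_dir(), "manifest.json"),
                      simplifyVector = TRUE)
}

# Feature matrices for the full study cohort (positive + free pools).
study_features <- function() {
  memo("study_features", {
    man <- study_manifest()
    ann <- study_annotations()
    fms <- lapply(seq_len(nrow(man$sessions)), function(i) {
      s <- man$sessions[i, ]
      rec <- read_recording(file.path(study_dir(), s$file),
                            subject_id = s$subject, session_id = s$session)
      build_feature_matrix(
        preprocess_recording(rec, ann[ann$session_id == s$session, ]))
    })
    fm <- ictalarm:::rbind_feature_matrix(fms)
    pos_subjects <- man$subjects[man$positive]
    list(positive = ictalarm:::subset_rows(fm, fm$groups %in% pos_subjects),
         free = ictalarm:::subset_rows(fm, !(fm$groups %in% pos_subjects)),
         annotations = ann)
  })
}

# LOSO run of the xgboost configuration over the study cohort, with the
# seizure-free pool scored per fold.
study_loso <- function() {
  memo("study_loso", {
    sf <- study_features()
    run_loso(sf$positive, model_spec("xgboost"), loso_config(seed = 42L),
             free_fm = sf$free)
  })
}

# Small separable Gaussian feature matrix: `n_subj` subjects, two
# informative features out of p, for fast model-level tests.
toy_feature_matrix <- function(n_subj = 4L, n_per = 80L, p = 10L,
                               prev = 0.2, effect = 2.5, seed = 1L) {
  set.seed(seed)
  n <- n_subj * n_per
  y <- rbinom(n, 1, prev)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- X[, 1] + effect * y
  X[, 2] <- X[, 2] - effect * y
  colnames(X) <- c(sprintf("CH%d__feat%d", rep(1:5, each = 2), rep(1:2, 5)))[seq_len(p)]
  groups <- rep(sprintf("t%02d", seq_len(n_subj)), each = n_per)
  ictalarm:::new_feature_matrix(
    X, labels = y, groups = groups,
    meta = data.frame(subject = groups,
                      session = paste0(groups, "_r01"),
                      start_s = rep(seq(0, by = 2.5, length.out = n_per),
                                    n_subj),
                      overlap_frac = as.numeric(y)))
}

# Brute-force event extraction: scan all maximal runs directly.
brute_force_events <- function(dec, min_len = 3L) {
  n <- length(dec)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (dec[i] == 1L) {
      j <- i
      while (j < n && dec[j + 1L] == 1L) j <- j + 1L
      if (j - i + 1L >= min_len) out[[length(out) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}
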