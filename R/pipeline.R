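# Configuration-driven orchestration: YAML config -> staged pipeline
# (simulate -> preprocess+features -> train -> evaluate -> explain ->
# stats -> report) with per-run artifact directories, a resolved config
# snapshot, parameter logging, and a single global seed (default 42).

#' Default pipeline configuration
#'
#' @param seed global seed (default 42).
#' @return nested configuration list; see [validate_config()] for the
#'   schema.
#' @export
default_config <- function(seed = 42L) {
  list(
    seed = as.integer(seed),
    data = list(mode = "synthetic", dir = NULL, line_noise_hz = 60,
                unit_scale = 1),
    synth = list(n_subjects = 6L, n_free_subjects = 3L,
                 sessions_per_subject = 1L, session_length_s = 600,
                 n_channels = 23L, seizures_per_subject = 2L,
                 seizure_len_s = c(20, 40), ictal_theta_gain = 3,
                 ictal_amp_gain = 1.5, background_slope = 1),
    preprocess = list(band = c(0.5, 40), window_s = 5, hop_s = 2.5),
    features = list(welch_nperseg = 256L, sampen_m = 2L,
                    sampen_r_factor = 0.2, permen_order = 4L),
    harmonize = list(collinearity_threshold = 0.95,
                     collinearity_sample_cap = 20000L,
                     balance_max_ratio = 20),
    models = list(names = "xgboost", calibration_frac = 0.2),
    events = list(threshold = 0.5, smooth_window = 5L, min_len = 3L),
    explain = list(top_k = 10L, stability_k = 20L,
                   lime_n_perturb = 300L),
    stats = list(fa_limit = 0.5, bootstrap_B = 2000L, ece_bins = 10L)
  )
}

#' Validate a pipeline configuration
#'
#' Checks types and ranges; accumulates all offending keys into a single
#' schema error.
#'
#' @param cfg configuration list (see [default_config()]).
#' @return `cfg`, invisibly, on success.
#' @export
validate_config <- function(cfg) {
  errs <- character()
  chk <- function(ok, key, why) {
    if (!isTRUE(ok)) errs <<- c(errs, paste0(key, ": ", why))
  }
  chk(is_scalar_number(cfg$seed), "seed", "must be a number")
  chk(cfg$data$mode %in% c("synthetic", "edf"), "data.mode",
      "must be 'synthetic' or 'edf'")
  chk(cfg$data$line_noise_hz %in% c(50, 60), "data.line_noise_hz",
      "must be 50 or 60")
  sw <- cfg$events$smooth_window
  chk(is_scalar_number(sw) && sw %% 2 == 1 && sw >= 3 && sw <= 11,
      "events.smooth_window", "must be odd and in 3..11")
  chk(is_scalar_number(cfg$events$threshold) &&
        cfg$events$threshold > 0 && cfg$events$threshold < 1,
      "events.threshold", "must be in (0, 1)")
  chk(is_scalar_number(cfg$events$min_len) && cfg$events$min_len >= 1,
      "events.min_len", "must be >= 1")
  chk(length(cfg$preprocess$band) == 2 &&
        cfg$preprocess$band[1] < cfg$preprocess$band[2],
      "preprocess.band", "must be an increasing pair")
  chk(all(cfg$models$names %in%
            c("xgboost", "extra_trees", "random_forest", "logistic")),
      "models.names", "unknown or unavailable model name")
  chk(is_scalar_number(cfg$harmonize$balance_max_ratio) &&
        cfg$harmonize$balance_max_ratio >= 1,
      "harmonize.balance_max_ratio", "must be >= 1")
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  invisible(cfg)
}

#' Read a YAML pipeline configuration
#'
#' Missing keys fall back to [default_config()] values.
#'
#' @param path YAML file.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
  cfg
}

pipe_log <- function(run_dir, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(msg, "\n", sep = "", file = file.path(run_dir, "run.log"),
      append = TRUE)
  invisible(msg)
}

cohort_feature_matrices <- function(cfg, data_dir, run_dir) {
  manifest <- jsonlite::read_json(file.path(data_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ann <- parse_annotations(file.path(data_dir, manifest$annotations_file))
  fcfg <- feature_config(welch_nperseg = cfg$features$welch_nperseg,
                         sampen_m = cfg$features$sampen_m,
                         sampen_r_factor = cfg$features$sampen_r_factor,
                         permen_order = cfg$features$permen_order)
  sessions <- manifest$sessions
  fms <- list()
  for (i in seq_len(nrow(sessions))) {
    s <- sessions[i, ]
    path <- file.path(data_dir, s$file)
    rec <- tryCatch(
      read_recording(path, line_noise_hz = cfg$data$line_noise_hz,
                     subject_id = s$subject, session_id = s$session,
                     unit_scale = cfg$data$unit_scale),
      error = function(e) {
        pipe_log(run_dir, "SKIP ", path, ": ", conditionMessage(e))
        NULL
      })
    if (is.null(rec)) next
    ints <- ann[ann$session_id == s$session, , drop = FALSE]
    segs <- preprocess_recording(rec, ints, band = cfg$preprocess$band,
                                 window_s = cfg$preprocess$window_s,
                                 hop_s = cfg$preprocess$hop_s)
    fms[[s$session]] <- build_feature_matrix(segs, fcfg)
    pipe_log(run_dir, "features: ", s$session, " -> ",
             nrow(fms[[s$session]]$values), " segments")
  }
  fm_all <- rbind_feature_matrix(fms)
  pos_subjects <- manifest$subjects[manifest$positive]
  list(positive = subset_rows(fm_all, fm_all$groups %in% pos_subjects),
       free = if (any(!manifest$positive)) {
         subset_rows(fm_all, !(fm_all$groups %in% pos_subjects))
       } else NULL,
       annotations = ann)
}

#' Run the seizure-detection pipeline
#'
#' Commands: `simulate` (write the synthetic cohort), `features`
#' (ingest + preprocess + feature matrix), `train` (LOSO + calibration),
#' `evaluate` (event metrics, FA/24 h, zero-FA frontier), `explain`
#' (SHAP rankings, stability, consistency), `stats` (equivalence,
#' bootstrap, calibration quality), `report` (merged JSON), or `all`.
#' Artifacts, a resolved config snapshot (`config.yaml`) and `run.log`
#' are written under `run_dir`.
#'
#' @param config a configuration list ([default_config()]) or a YAML
#'   path.
#' @param command one of the stage names above.
#' @param run_dir artifact directory (default: a fresh timestamped
#'   directory under `tempdir()`).
#' @return the run directory, invisibly; stage outputs are files and a
#'   `state.rds`-free environment is not kept (stages re-read artifacts).
#' @export
run_pipeline <- function(config = default_config(),
                         command = c("all", "simulate", "features", "train",
                                     "evaluate", "explain", "stats",
                                     "report"),
                         run_dir = NULL) {
  command <- match.arg(command)
  cfg <- if (is.character(config)) read_config(config) else {
    validate_config(utils::modifyList(default_config(), config))
    utils::modifyList(default_config(), config)
  }
  run_dir <- run_dir %||%
    file.path(tempdir(), paste0("ictalarm-run-",
                                format(Sys.time(), "%Y%m%d-%H%M%S")))
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(run_dir, "config.yaml"))
  pipe_log(run_dir, "command=", command, " seed=", cfg$seed)

  stages <- if (command == "all") {
    c("simulate", "features", "train", "evaluate", "explain", "stats",
      "report")
  } else command
  state <- new.env(parent = emptyenv())
  for (stage in stages) {
    pipe_log(run_dir, "stage: ", stage)
    switch(stage,
      simulate = {
        if (cfg$data$mode == "synthetic") {
          data_dir <- cfg$data$dir %||% file.path(run_dir, "cohort")
          params <- do.call(synth_params,
                            c(cfg$synth, list(seed = cfg$seed,
                                              line_noise_hz =
                                                cfg$data$line_noise_hz)))
          generate_cohort(params, data_dir)
          state$data_dir <- data_dir
          pipe_log(run_dir, "cohort written to ", data_dir)
        } else {
          state$data_dir <- cfg$data$dir
          pipe_log(run_dir, "edf mode: using ", cfg$data$dir)
        }
      },
      features = {
        dd <- state$data_dir %||% cfg$data$dir %||%
          file.path(run_dir, "cohort")
        fm <- cohort_feature_matrices(cfg, dd, run_dir)
        state$fm <- fm
        write_feature_matrix(fm$positive,
                             file.path(run_dir, "features_positive.csv"))
        if (!is.null(fm$free)) {
          write_feature_matrix(fm$free,
                               file.path(run_dir, "features_free.csv"))
        }
      },
      train = {
        fm <- state$fm %||% stop("run the features stage first")
        specs <- lapply(cfg$models$names, model_spec, seed = cfg$seed)
        lcfg <- loso_config(seed = cfg$seed,
                            collinearity_threshold =
                              cfg$harmonize$collinearity_threshold,
                            collinearity_sample_cap =
                              cfg$harmonize$collinearity_sample_cap,
                            balance_max_ratio =
                              cfg$harmonize$balance_max_ratio,
                            calibration_frac = cfg$models$calibration_frac)
        state$loso <- run_loso(fm$positive, specs, lcfg, free_fm = fm$free)
        segsum <- summary(state$loso)
        utils::write.csv(segsum, file.path(run_dir, "segment_metrics.csv"),
                         row.names = FALSE)
        for (m in names(state$loso$models)) {
          kept <- lapply(state$loso$models[[m]], function(f) f$kept_features)
          jsonlite::write_json(kept,
                               file.path(run_dir,
                                         paste0("kept_features_", m, ".json")),
                               auto_unbox = FALSE, pretty = TRUE)
        }
      },
      evaluate = {
        loso <- state$loso %||% stop("run the train stage first")
        ev <- evaluate_events(loso, state$fm$annotations,
                              threshold = cfg$events$threshold,
                              smooth_window = cfg$events$smooth_window,
                              min_len = cfg$events$min_len,
                              window_s = cfg$preprocess$window_s)
        state$event_metrics <- ev
        utils::write.csv(ev, file.path(run_dir, "event_metrics.csv"),
                         row.names = FALSE)
        fr <- zero_fa_frontier(data.frame(patient = ev$patient,
                                          model = ev$model,
                                          sensitivity = ev$event_sensitivity,
                                          fa_per_24h = ev$fa_per_24h))
        state$frontier <- fr
        jsonlite::write_json(fr, file.path(run_dir, "frontier.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      explain = {
        loso <- state$loso %||% stop("run the train stage first")
        if (!"xgboost" %in% names(loso$models)) {
          pipe_log(run_dir, "explain: no xgboost model; skipped")
        } else {
          folds <- loso$models[["xgboost"]]
          fmpos <- state$fm$positive
          rankings <- list()
          for (s in names(folds)) {
            f <- folds[[s]]
            Xtest <- fmpos$values[fmpos$groups == s, f$kept_features,
                                  drop = FALSE]
            rankings[[s]] <- shap_global(f$model, Xtest)
          }
          state$shap_rankings <- list(xgboost = rankings)
          stab <- stability_table(state$shap_rankings,
                                  k = cfg$explain$stability_k)
          utils::write.csv(stab, file.path(run_dir, "shap_stability.csv"),
                           row.names = FALSE)
          topo <- channel_topography(rankings[[1]])
          jsonlite::write_json(as.list(topo),
                               file.path(run_dir, "topography.json"),
                               auto_unbox = TRUE, digits = NA, pretty = TRUE)
        }
      },
      stats = {
        ev <- state$event_metrics %||% stop("run the evaluate stage first")
        out <- list()
        for (m in unique(ev$model)) {
          fa <- ev$fa_per_24h[ev$model == m]
          if (all(is.finite(fa)) && length(fa) >= 2) {
            eq <- equivalence_fa_test(fa, limit = cfg$stats$fa_limit)
            ci <- bootstrap_ci(fa, B = cfg$stats$bootstrap_B,
                               seed = cfg$seed)
            out[[m]] <- list(fa_mean = eq$mean, fa_sd = eq$sd,
                             fa_p = eq$p, fa_ci = ci)
          }
        }
        loso <- state$loso
        for (m in names(loso$models)) {
          probs <- unlist(lapply(loso$models[[m]], function(f)
            f$calibrated_probs))
          labs <- unlist(lapply(loso$models[[m]], function(f) f$labels))
          cq <- calibration_quality(probs, labs, bins = cfg$stats$ece_bins)
          out[[m]]$ece <- cq$ece
          out[[m]]$brier <- cq$brier
        }
        state$stats <- out
        jsonlite::write_json(out, file.path(run_dir, "stats.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      },
      report = {
        report <- list(
          seed = cfg$seed,
          segment_metrics = if (!is.null(state$loso))
            summary(state$loso) else NULL,
          event_metrics = state$event_metrics,
          frontier = state$frontier,
          stats = state$stats)
        jsonlite::write_json(report, file.path(run_dir, "report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             dataframe = "rows")
        pipe_log(run_dir, "report written")
      })
  }
  invisible(run_dir)
}
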