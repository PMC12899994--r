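# ictalarm

Patient-independent seizure detection from multichannel scalp EEG, with
event-level false-alarm control and built-in explainability.

Continuous EEG monitoring produces hours of signal in which seizures
occupy minutes. A clinically usable detector must keep event-level
sensitivity high while holding false alarms near the accepted limit of
0.5 per 24 h — a far stricter requirement than segment-level accuracy.
ictalarm implements a complete pipeline for this problem:

* **Ingestion** — EDF recordings (256 Hz, bipolar 10–20 montage;
  polyphase resampling otherwise) and seizure annotation tables
  (`session,onset_s,offset_s` CSV, plus a CHB-MIT `summary.txt`
  adapter), with a channel-intersection policy across sessions.
* **Conditioning** — zero-phase Butterworth band-pass (0.5–40 Hz) and
  mains notches, common average reference, per-recording z-scoring
  `x' = (x − μ)/(σ + ε)`, then 5 s windows with 50% overlap (1280
  samples), labeled ictal when ≥ 50% of the window lies inside an
  annotated seizure.
* **Features** — 32 per-channel descriptors over time (Hjorth
  parameters, line length, zero crossings, RMS/IQR/peak-to-peak,
  Teager–Kaiser energy ψ[n] = x[n]² − x[n−1]x[n+1]), spectrum (Welch
  band powers δ–γ, ratios, spectral entropy, median/edge frequency,
  1/f slope) and nonlinear dynamics (sample entropy m = 2, r = 0.2·SD;
  permutation entropy order 4), plus cross-channel lateralization and
  asymmetry summaries — 746 named columns on a 23-channel montage.
* **Training** — leave-one-subject-out (LOSO) cross-validation of
  XGBoost / Extra Trees / Random Forest / logistic pipelines with fixed
  hyperparameters; per-fold cleaning, |r| ≥ 0.95 collinearity pruning,
  20:1 undersampling, isotonic probability calibration on a stratified
  20% split; `scale_pos_weight` capped at 100.
* **Events** — median smoothing of the probability stream, ≥ 3
  consecutive positive windows per event, event sensitivity
  TP_events/TrueEvents, FA/24 h on a seizure-free pool, and the
  per-patient zero-false-alarm frontier.
* **Explainability** — exact double-precision TreeSHAP (additivity
  `base + Σφ = margin` to machine precision), LIME-style ridge
  surrogates, SHAP–LIME agreement (Jaccard and the asymmetric overlap),
  channel topography, top-k ablation, cross-fold stability tables.
* **Statistics** — one-sided equivalence test of FA/24 h against the
  0.5/day limit, bootstrap CIs, exact Wilcoxon/Mann–Whitney
  comparisons, decile-binned ECE and Brier score, permutation nulls
  for ranking consistency.
* **Synthetic cohorts** — a seeded generator (1/f background + alpha
  rhythm; amplitude-modulated theta on focus channels during seizures)
  writes EDF + annotations + manifest, so the entire pipeline runs and
  is tested without clinical data.

## A worked example

Generate a small cohort, train under LOSO, and evaluate events:

```r
library(ictalarm)

params <- synth_params(n_subjects = 3, n_free_subjects = 1,
                       session_length_s = 240, seed = 7)
dir <- file.path(tempdir(), "cohort")
manifest <- generate_cohort(params, dir)
ann <- parse_annotations(file.path(dir, "annotations.csv"))

fms <- lapply(manifest$sessions, function(s) {
  rec <- read_recording(file.path(dir, s$file), subject_id = s$subject,
                        session_id = s$session)
  build_feature_matrix(
    preprocess_recording(rec, ann[ann$session_id == s$session, ]))
})
fm  <- ictalarm:::rbind_feature_matrix(fms)
pos <- ictalarm:::subset_rows(fm, grepl("^s", fm$groups))
fre <- ictalarm:::subset_rows(fm, grepl("^f", fm$groups))

res <- run_loso(pos, model_spec("xgboost"), loso_config(seed = 42),
                free_fm = fre)
summary(res)
```

```
    model subject       auc    recall precision        f1
1 xgboost     s01 1.0000000 1.0000000         1 1.0000000
2 xgboost     s02 1.0000000 0.9600000         1 0.9795918
3 xgboost     s03 0.9793757 0.9615385         1 0.9803922
```

Each row is one LOSO fold: the model never saw the listed subject
during training, and the segment-level AUC/recall/precision describe
its 5 s-window discrimination on that subject. Event-level results and
the zero-false-alarm frontier follow from:

```r
evaluate_events(res, ann)                  # fixed 0.5 threshold
zero_fa_operating_points(res, ann)         # per-fold zero-FA frontier
```

The whole chain is also driveable from a YAML configuration:

```r
run_pipeline(default_config(seed = 42), "all")
```

or from a shell via `inst/scripts/ictalarm-run.R`.

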