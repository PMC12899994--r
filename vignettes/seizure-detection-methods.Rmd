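---
title: "Calibrated ensemble seizure detection: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated ensemble seizure detection: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ictalarm)
```

## The detection problem

Scalp EEG monitoring of people with epilepsy produces hours of
multichannel signal in which electrographic seizures occupy a few
minutes at most. A clinically usable detector must satisfy two
competing constraints at once: high *event-level* sensitivity (every
seizure episode raises at least one alarm) and a false-alarm rate near
the accepted limit of 0.5 alarms per 24 h — far stricter than what
segment-level accuracy numbers suggest. ictalarm implements a
patient-independent pipeline for this problem: interpretable features
from 5 s windows, gradient-boosted and bagged ensembles under strict
leave-one-subject-out (LOSO) cross-validation, isotonic probability
calibration, temporal smoothing, and event-level evaluation, with SHAP
and LIME attributions to connect model behavior back to
neurophysiology.

## Signal conditioning

Recordings enter as EDF at 256 Hz on a bipolar 10-20 montage (a
channel-intersection policy keeps only channels common to all of a
subject's sessions, in the first session's order; recordings at other
rates are polyphase-resampled). Conditioning follows the order
band-pass, notch, common average reference, z-score:

* **Band-pass 0.5–40 Hz**, fourth-order Butterworth applied
  forward-backward (zero phase; effective order 8). This bracket keeps
  the canonical delta through gamma rhythms and removes DC drift and
  EMG contamination.
* **Notch** at the mains frequency and its first harmonic (60/120 Hz
  or 50/100 Hz), implemented as 2 Hz-wide second-order band-stops. The
  paper-level protocol names no Q; 2 Hz is narrow enough to leave the
  gamma band intact.
* **Zero-phase application.** No installed routine provided padded,
  steady-state-initialized zero-phase filtering, so the package applies
  filters with a direct-form-II-transposed kernel, symmetric signal
  extension, and step-steady-state initial conditions. Edge behavior is
  a real property of any finite zero-phase filter: a 2 Hz-wide notch
  has an impulse response of hundreds of milliseconds, so the first and
  last second of a recording are imperfectly filtered. The package's
  tests assert attenuation and the zero-phase identity on the
  steady-state interior; windows at recording edges inherit the
  (small) residual.
* **Common average reference**, subtracting the instantaneous
  across-channel mean.
* **Per-channel z-scoring** over the continuous recording,
  `x' = (x - mu)/(sigma + 1e-8)`, with population-SD convention.

Segmentation uses 5 s windows with a 2.5 s hop (1280 samples at
256 Hz), fully contained in the recording — the last partial window is
dropped, the simplest deterministic rule. A window is labeled ictal
when at least half of it (overlap fraction >= 0.5, closed inequality)
lies inside an annotated seizure interval; intervals are half-open
`[onset, offset)` seconds and overlapping annotations are merged.

## The feature bank

Per channel and window, 32 features across three domains: moments
(mean, variance, skewness, excess kurtosis), line length,
zero-crossing rate, Hjorth activity/mobility/complexity (first
differences, unscaled by the sampling rate — a fixed monotone
convention), RMS, IQR, peak-to-peak, and mean Teager–Kaiser energy;
Welch band powers (Hann, 256-sample segments, 50% overlap) absolute
and relative over delta/theta/alpha/beta/gamma, the ratios
theta/alpha, beta/alpha and (beta+gamma)/(alpha+theta), spectral
entropy normalized to [0,1] over 0.5–40 Hz, median and 95% edge
frequency, and the 1/f slope fit by ordinary least squares over
1–40 Hz in log-log (the protocol names no range; 1–40 Hz avoids the
DC-adjacent bin); sample entropy (m = 2, r = 0.2 SD, Chebyshev
distance, self-matches excluded, natural log — switchable to base 2)
and permutation entropy (order 4, delay 1, normalized by log 4!).
Cross-channel summaries add the maximum RMS over channels, per-band
hemispheric lateralization indices (odd/even 10-20 electrode indices
of a bipolar channel's first electrode; midline excluded), and mean
adjacent-band asymmetries. For 23 channels this yields 746 named
columns (`{CHANNEL}__{feature}` plus globals) — the protocol's "27
features per channel" headline undercounts its own enumerated bank, so
the package implements the full enumeration and documents the count.

Two deliberate exclusions: the per-window seizure-overlap fraction is
computed and carried as metadata but is *not* a model input — as a
direct function of the labels it would be leakage — and no wavelet or
connectivity features are included.

When no sample-entropy template pair matches at tolerance r, the value
is capped at `log(#template pairs)` with a warning rather than
returning infinity; the cap is the information-theoretic ceiling of
the estimator.

## Harmonization, models, and the LOSO protocol

Within each training fold (never on held-out data): non-finite entries
are replaced by column medians and entries beyond five training SDs
are winsorized two-sided to the 0.1/99.9 percentile bounds (the
protocol mixes the two formulations; the package implements the
literal combination). Values remain double precision — R has no native
float32 storage, and the cast is a storage detail with no effect on
any asserted value. A greedy collinearity filter over Pearson
correlations (|r| >= 0.95, computed on a seeded row subsample) keeps
the earlier member of each offending pair; zero-variance columns have
undefined correlation, treated as zero and kept. Negatives are then
undersampled to at most 20:1 against positives. Whether the
collinearity pass is global or per fold is ambiguous in the protocol;
per fold is the leakage-safe reading and is the default. A
two-component PCA on standardized features is available as a
diagnostic.

The model suite fixes all hyperparameters: XGBoost (200 trees,
learning rate 0.1, depth 6, subsample and colsample 0.8, gamma 0.1,
min_child_weight 5, `scale_pos_weight = min(neg/pos, 100)`), Extra
Trees and Random Forest (100 trees, sqrt feature sampling, minimum
leaf 5, balanced class weights), and an L2 logistic baseline (C = 1.0
equivalence via ridge). LightGBM and CatBoost have no R backend in
this toolchain; their specifications raise an informative error, and
all cross-model statistics operate on whichever models are present.
Each pipeline standardizes features with training-fold statistics
before the classifier.

In each LOSO fold one seizure-positive subject is held out entirely;
cleaning, collinearity filtering, balancing, standardization, model
fitting, and calibration all see only the remaining subjects. The
per-fold seed is derived from the held-out subject's identity, not its
position, so fold results are bitwise-invariant to the composition of
the surrounding data — the property the leakage-guard test asserts.
Isotonic regression is fit on a stratified 20% calibration split of
the training rows (raw score = the model's positive-class
probability), linearly interpolated between knots and clamped to
[0,1]; a single-class split degrades to the identity map with a
warning. Calibration precedes smoothing and thresholding
(calibrate -> smooth -> threshold); the alternative order is a
configuration switch, as the protocol lists the two steps separately.

## Events and the zero-false-alarm frontier

Calibrated probabilities are median-smoothed per session (window 5 by
default, the midpoint of the admissible 3–11 range; symmetric edge
padding), thresholded at 0.5, and grouped into events as maximal runs
of at least three consecutive positive windows. A true seizure counts
as detected when any predicted event overlaps it in time; each true
event counts once however many predictions overlap it. Event
sensitivity is detected/true events; specificity and precision are
segment-level; event F1 combines event-level precision with event
sensitivity. Zero denominators yield NA with a flag, never zero.
FA/24 h counts predicted events with no overlap with any true seizure,
normalized by monitored hours, and is invariant to how the monitoring
period is split into sessions. Each fold's model also scores the
seizure-free pool, giving per-fold FA values for the equivalence test
against the 0.5/day limit.

Two operating-point modes are provided, because how the zero-FA
operating point was reached in the source protocol (fixed 0.5
threshold observed post hoc vs. per-fold threshold calibration) is not
stated: a fixed-threshold evaluation, and a per-fold sweep that
selects the smallest threshold with zero false events on the
seizure-free pool. The frontier (per patient, the configuration of
highest sensitivity among those with zero false alarms) is computed
from either. Neither mode is asserted as the original one.

## Explainability

SHAP attributions are computed by an exact TreeSHAP implementation in
double precision over the booster's dumped tree structure, on the
margin (log-odds) scale. The in-library float32 implementation leaves
additivity residuals of order 1e-5 on 200-tree models; recomputing
both the attributions and the margin from the same double-precision
traversal makes `base + sum(phi) = margin` hold to machine precision,
and split evaluation replicates the booster's float32 comparisons so
the traversal matches the fitted model exactly. The implementation is
cross-checked against the library's attributions (float tolerance) and
against brute-force Shapley enumeration on hand-built trees. Global
importance is the mean absolute attribution per feature.

LIME-style local surrogates draw seeded Gaussian perturbations around
a sample (training-fold SDs; zero-variance features are not
perturbed), weight them by a Gaussian proximity kernel (width
0.75*sqrt(p)), fit a ridge surrogate in closed form, and return the
top-k coefficients by absolute weight.

Explanation agreement is reported two ways: the asymmetric overlap
|F_SHAP ∩ F_LIME| / |F_LIME| as the protocol prints it, and the
Jaccard index |∩|/|∪|. The printed formula is not the Jaccard index,
yet the published agreement values are consistent with Jaccard (3
shared of 10 vs 10 gives 3/17 ≈ 0.18); the package therefore reports
Jaccard as the headline statistic and the asymmetric ratio alongside.
Default top-k for agreement is 10. Channel topography sums importances
per channel and min-max normalizes to [0,1] (a constant vector maps to
all ones, the documented degenerate case). Stability tables count
top-20 appearances per (fold, model) and per-subject coverage;
ablation re-runs the LOSO protocol on top-k feature subsets for
k in {5, 10, 15, 20, 25, 30}.

## Statistics

The FA equivalence test is a one-sided t-test of H0: mean FA/24h >=
0.5 against the lower tail — a superiority-to-bound test, which is how
the protocol states its null, not a TOST pair. All-equal samples have
s = 0, where a textbook t statistic is undefined; published tables
nevertheless print p = 0.0000 for all-zero FA columns, so the package
defines the degenerate rule p = 0 when the mean is below the limit and
1 otherwise. Bootstrap CIs are percentile intervals over 5000 seeded
resamples of the mean. Paired comparisons use the exact Wilcoxon
signed-rank distribution (zero differences dropped; the Pratt variant
is a configuration option) with ties falling back to the corrected
normal approximation, plus Mann–Whitney U; the test suite checks the
exact path against full 2^n sign enumeration. Calibration quality is
decile-binned ECE (equal-width bins, empty bins skipped) and the Brier
score. Ranking-consistency significance uses a permutation null that
relabels feature identities within the universe, 1000 permutations,
with the add-one p-value convention.

## The synthetic cohort: what it does and does not emulate

Every stage is testable without clinical data through the generator.
Background EEG is 1/f Gaussian noise (slope 1) plus an
amplitude-modulated 8–13 Hz alpha component, scaled to 30 uV RMS.
Ictal episodes add an amplitude-modulated 4–8 Hz rhythm of
`(theta_gain - 1)` channel SDs with a raised amplitude envelope
(`amp_gain`), raised-cosine tapered, at full gain on three focus
channels (FT9-FT10, T7-P7, FP1-F3 — temporal/frontal derivations known
to dominate ictal attributions) and 25% elsewhere, emulating focal
onset with attenuated spread. This is the simplest signal carrying the
biomarkers the pipeline is built around: theta-band power, RMS/IQR
amplitude variability, Hjorth activity.

The default study conditions are 6 seizure-positive and 3 seizure-free
subjects, one 600 s session each, 23 channels at 256 Hz, two seizures
of 20–40 s per positive subject — a segment prevalence of about 10%,
inside the 8–12% band typical of curated seizure corpora. Ten-minute
sessions are the package's desk-scale choice: they preserve the
prevalence structure, the LOSO fold geometry, and the free-pool FA
assessment of hours-long clinical sessions at a size every
installation can regenerate from a seed in minutes; reproducing the
published clinical-corpus tables is explicitly out of scope. All
randomness derives from one seed via per-subject/session/interval
substreams, so cohorts are byte-identical across runs.

What passing tests on this cohort show: the pipeline's plumbing,
leakage safety, calibration, event logic, and attribution machinery
are correct, and the detector recovers a solvable focal-theta
signature across subjects. What they do not show: robustness to
artifacts (eye blink, EMG, electrode pops), inter-subject morphology
diversity beyond spectral jitter, non-theta seizure types, or
annotation noise — real-data performance claims require real data.

## Numerical choices and degenerate inputs

Constant channels z-score to zero through the epsilon guard; constant
windows return zero mobility/complexity/TKEO and zero spectral
features; all-zero windows short-circuit the spectral bank. Collinear
ties break by canonical column order. EDF quantization is 16-bit with
per-channel physical scaling chosen from the observed range, so
round-trip error is bounded by one quantization step; physical bounds
are written in the exact ASCII the reader parses back. Event matching
uses strict interval overlap on half-open intervals. The isotonic map
interpolates linearly between calibration knots (monotone by
construction) and extrapolates by clamping to the extreme knot values.

## Known limitations

Single-rate EDF only (no per-channel rates, no re-montaging from
referential recordings); no artifact simulation or rejection beyond
winsorization; no streaming/online latency measurement (detection
latency is descriptive output — the 50% overlap rule alone does not
determine a latency bound); SHAP requires the xgboost backend (bagged
models are evaluated but not tree-exactly attributed); and the
LightGBM/CatBoost columns of cross-model tables are absent in this
toolchain.
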