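---
title: "Estimating intravascular volume status from Valsalva PPG waveforms: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating intravascular volume status from Valsalva PPG waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgvalsalva)
```

## The problem

In decompensated cirrhosis, diuretic dosing is guided by an estimate of
*intravascular* volume that is hard to obtain: physical examination is
unreliable, BNP is only weakly informative, and the gold standard —
invasively measured left-ventricular end-diastolic or pulmonary capillary
wedge pressure ("filling pressure") — requires catheterization. A
physiologic shortcut exists: during a standardized Valsalva maneuver
(forced expiration to a 25 mmHg mouth-pressure target for 10 s), cardiac
preload falls and the fingertip photoplethysmography (PPG) pulse amplitude
attenuates. In volume-overloaded patients this attenuation is blunted, so
the *end-strain to rest amplitude ratio* — and richer waveform features
around it — carries information about filling pressure.

`ppgvalsalva` implements that analysis as a fully testable pipeline:

1. a synthetic cohort generator in which the attenuation response encodes a
   latent filling pressure,
2. beat detection and per-beat/per-window feature extraction,
3. candidate-pool expansion and greedy forward selection capped at three
   features,
4. cross-validated regression of filling pressure and classification of
   volume overload against dummy and BNP-only baselines, and
5. Bland–Altman agreement reporting.

No patient-level data ship with the package; every analysis runs on
simulated cohorts whose population parameters mirror a realistic
catheterization cohort (about 35% overload prevalence; group filling
pressures 23.67 (6.00) vs 10.59 (3.02) mmHg; mean age 62.6 (10.4) years).

## The generator

### Filling pressure

Pressure is a two-component truncated-normal mixture: with probability
`prevalence_overload` (0.35) a draw from N(23.67, 6.00) truncated to
(15, Inf) mmHg, otherwise from N(10.59, 3.02) truncated to (0, 15]. Draws
use the inverse-CDF method, so zero-SD components degenerate cleanly and
the truncation bounds are exact. Note that truncation shifts the realized
group means away from the component means (to about 24.6 and 10.2 mmHg);
the tests assert against rejection-sampling oracle values rather than the
component parameters.

### The attenuation dose–response

The generator's central modeling choice is the map from filling pressure
*P* to the end-strain amplitude ratio

\[
r_\mathrm{end}(P) \;=\; r_{\min} + (1 - r_{\min})\,
  \operatorname{logistic}\!\left(\frac{P - P_0}{s}\right),
\]

with defaults \(r_{\min} = 0.4\), \(P_0 = 15\) mmHg, \(s = 3\) mmHg. At low
pressure the pulse amplitude falls to ~40% of rest (the normal response);
at high pressure the ratio approaches 1 (the blunted response). The
midpoint sits at the 15 mmHg clinical overload cutoff, placing the steepest
part of the dose–response exactly where the classification decision lives,
so the task is learnable without being trivial at the boundary. No
quantitative dose–response is established in the literature for this
setting; this logistic form is a deliberate simulation choice, and the
package's validation is therefore *parameter recovery* on synthetic
cohorts, not reproduction of any particular patient series.

### Pulse train and envelope

Each trial is 30 s rest, 10 s strain, 20 s recovery at 100 Hz (a typical
pulse-oximeter rate). Beats follow the subject's heart rate
(N(72, 9) bpm truncated to 45–110) with 3% beat-to-beat interval jitter.
Each beat is a stereotyped asymmetric template — a fast gamma-like upstroke
peaking at 18% of the beat period, a slower decay, and a small dicrotic
bump — anchored to zero at both beat edges and normalized to unit peak
height. Beat *i*'s amplitude is `baseline_amplitude` times an envelope
m(t) evaluated at its peak: 1 during rest, a linear decline to
\(r_\mathrm{end}\) over the **first half of the strain** followed by a
plateau, and a linear return to 1 over the first 5 s of recovery. The
early-decline/plateau shape reflects the physiology — the amplitude
reduction develops during early strain and is maximal at end-strain — and
makes the last-5-s strain window a clean readout of \(r_\mathrm{end}\).
White noise (`noise_sd`, default 0.02 AU against a 1 AU baseline) and a
slow sinusoidal baseline drift (0.05 AU, 12 s period) are added on top.

### BNP

BNP is log-linear in pressure:
`log BNP = 4.5 + 0.045 P + N(0, 0.58)`. The slope and noise were chosen
once so that a BNP-only OLS of pressure attains a cross-validated
R² of roughly 0.1–0.35 at n = 200 — a deliberately weak comparator, as
observed clinically. A steeper slope with proportionally larger noise
produces the same log-scale correlation but a raw-scale lognormal tail so
heavy that the comparator's CV R² becomes erratic (occasionally
catastrophically negative when an extreme BNP value lands in a held-out
fold); the flatter parameterization keeps the comparator weak *and*
stable. A consequence is that the simulated BNP group separation is milder
than the (noise-inflated, small-sample) group means sometimes reported in
real cohorts.

### Determinism

All randomness flows from `config$seed`: the cohort generator draws one
substream seed per subject, so cohorts are byte-identical for identical
`(n, config)` and subjects are reproducible independently of cohort size.

## Feature extraction

**Beat detection.** The signal is detrended with a centered 1.5 s moving
average and smoothed over 50 ms; candidate peaks need a 0.33 s refractory
gap (≤180 bpm) and must exceed 25% of the detrended signal's 99.5th
percentile. The threshold is a quantile, so detection is exactly
scale-invariant. Peaks are refined to the raw-signal maximum within
±0.1 s; feet are raw-signal minima between consecutive peaks; a beat is
(foot, peak, next foot).

**Per-beat metrics.** Amplitude is peak minus foot; width is measured at
half amplitude above the foot level with linear interpolation between
samples (the half-height convention is a choice — "width" alone is
ambiguous); AUC is the trapezoidal integral of the foot-level-subtracted
signal across the beat. Beats whose half-height level is never crossed are
dropped from all aggregates, with a message.

**Windows and ratios.** Aggregates are computed over the *last 5 s* of the
rest phase (`end_rest`) and of the strain phase (`end_valsalva`) — the 5 s
default targets the end-strain phase where the response is maximal, and is
tunable via `window_len`. Amplitude mean/SD use the n−1 sample SD;
`rms_power` is the RMS of the mean-subtracted raw samples in the window.
"RMS power" could also be read as the RMS of beat amplitudes or as squared
RMS; the signal-RMS reading is implemented, and the alternatives were
noted and rejected rather than mixed in. Ratios are oriented
end-Valsalva ÷ end-rest, so normal physiology gives ratios below 1; the
orientation is a pure reparameterization for every downstream model.

**Aggregation.** A subject's features are the arithmetic mean over their
valid trials (of three): the simplest unbiased aggregate. Trials that fail
extraction are dropped with a message; a subject with no valid trial is
dropped and logged.

## The candidate pool and the fixed final feature sets

The pool is built from ten bases — six window aggregates (`amp_rest`,
`amp_vals`, `sd_rest`, `sd_vals`, `width_rest`, `width_vals`), the three
ratios (`ratio_rms`, `ratio_auc`, `ratio_amplitude`), and `age` — plus all
squares `sq(x)` and all pairwise products `ix(x,y)`:
10 + 10 + 45 = 65 columns in a deterministic order (bases, squares,
interactions, each lexicographic; interaction arguments canonicalized
lexicographically). Ratios are included as bases in their own right, since
the interesting constructions (e.g. the interaction of the RMS-power and
AUC ratios) require them.

`final_model_features()` exposes fixed, pre-specified three-feature sets
per analysis case (e.g. for regression:
`ix(ratio_auc,ratio_rms)`, `ix(age,sd_rest)`, `ix(amp_vals,ratio_auc)`) so
analyses can be run either with a fresh forward search (the default) or
with the fixed sets; both paths are first-class because reusing
regression-selected features for classification and running a fresh
classification search are both defensible and the choice is surfaced as a
flag rather than resolved silently.

## Modeling

**Forward selection** is greedy and capped at `k = 3`: at each step the
candidate maximizing the in-sample criterion joins the model (regression:
OLS R²; classification: resubstitution accuracy of the chosen classifier).
Ties break toward the earlier pool column. The first step always admits
the best single candidate; afterwards selection stops unless a candidate
strictly improves the criterion, so the selection trace is strictly
increasing. Selection runs on the *full dataset*, not within CV folds —
deliberately mirroring the small-cohort practice this pipeline models,
where per-fold selection is too unstable; the three-feature cap is the
counterweight to the optimism this introduces. The permuted-target
controls in the acceptance suite quantify that optimism: with 65
candidates and n = 300 it amounts to at most a few hundredths of CV R².

**Regression** is OLS with an intercept via QR; exactly collinear columns
(pivot tolerance 1e-10 relative) are dropped with a warning. The
cross-validated R² uses a seeded shuffle into five folds, refits the fixed
feature set per training fold, and pools all held-out predictions:
`cv_r2 = 1 − Σ(y − ŷ_heldout)² / Σ(y − ȳ)²`.

**Classification** uses stratified seeded folds (the minority class is
dealt round-robin so every fold gets its share — at realistic prevalence a
plain shuffle can starve a fold of positives) and pools held-out scores
and labels before computing metrics once. Pooling keeps the dummy
baseline's identities exact: a constant-score majority-class dummy has
recall 0, precision 0 (the 0/0 convention), F1 0, specificity 1, and AUROC
exactly 0.5, regardless of fold composition. Per-fold averaging would blur
these into fold-size-dependent values. Note that at a cutoff where the
*positive* class is the majority, the dummy flips accordingly (recall 1,
specificity 0); the identities above hold whenever the negative class is
the majority, as at the primary 15 mmHg cutoff.

Five classifiers are provided with fixed, documented hyperparameters (no
tuning appears anywhere in the pipeline): LDA; logistic regression; KNN
with k = 5; a decision tree with depth ≤ 3; and an RBF-kernel SVM with
cost 1 and kernel scale 1/(p·var). KNN, SVM and logistic inputs are
z-scored using training-fold statistics only. AUROC scores are
positive-class posteriors (LDA, logistic, tree), folded vote fractions
(KNN), and oriented decision values (SVM). AUROC itself is the
Mann–Whitney rank statistic with midranks, identical to the all-pairs
count with ties scored one-half — the test suite verifies that identity
against a brute-force oracle.

**Bland–Altman** reports the mean difference (predicted − actual), 1.96-SD
limits of agreement (the standard multiplier), and the slope of difference
on mean with its p-value as a proportional-bias check. Both in-sample and
held-out variants are produced and labeled; the in-sample bias is exactly
zero by the OLS residual identity, so the held-out variant is the
informative one.

## What the generator does and does not emulate

It emulates: the trial protocol (three trials, 10 s strain at a 25 mmHg
target, rest between), a realistic pressure mixture and prevalence, the
attenuation physiology and its blunting with overload, pulse morphology
sufficient for amplitude/width/AUC features, measurement noise and
baseline drift, and a weakly informative BNP.

It does not emulate: motion artifacts, arrhythmia (excluded in the
clinical protocol this mirrors), respiratory modulation beyond a generic
drift, subject-level variability in the *shape* of the attenuation
response (every subject shares one dose–response curve), vascular-tone or
medication effects on pulse morphology, or device-specific transfer
functions. Passing tests therefore demonstrate that the pipeline recovers
the encoded physiology correctly and behaves sanely under noise — not that
these effect sizes would be attained in patients. On real cohorts of ~26
subjects, substantially lower CV performance is expected; on synthetic
cohorts of n = 300 the recovered CV R² is high precisely because the
generator's only obstacles are measurement noise and the logistic's
saturation at high pressure.

## Numerical choices and degenerate inputs

- Waveform text I/O: 6 significant digits for samples (round-trip
  tolerance 1e-5 AU), microsecond time resolution, uniform-spacing
  validation at 1e-6 s.
- Collinearity: columns pivoted out at 1e-10 relative tolerance, with a
  warning naming them; a still-deficient design is an error.
- Detection: fewer than two usable beats, a constant signal, or a window
  with fewer than two in-window beats raise typed errors
  (`ppgv_detection_error`, `ppgv_windowing_error`) that name the offending
  trial, so cohort-level extraction can drop and log rather than abort.
- Degenerate generator settings (zero SDs, zero noise) are exact limits,
  used heavily by the oracle tests.
- Problem sizes in the shipped tests and scripts were chosen to exercise
  the full pipeline at meaningful scale while keeping each suite quick:
  n = 300 for parameter recovery, 20 replicates of n = 200 for the
  BNP-ordering property, n = 10,000 (metadata-only) for calibration
  checks, and short-trial configurations for cohort-level unit tests.

## Known limitations

- The logistic dose–response and the envelope time course are simulation
  choices; only their qualitative shape (monotone, saturating, maximal at
  end-strain) is physiologically grounded.
- The pipeline models a single operator-free maneuver; no quality control
  for inadequate strain effort is implemented beyond the annotation's
  target pressure field.
- Feature selection on the full dataset is intentionally optimistic (see
  above); consumers who need honest generalization estimates at scale
  should nest the selection, which this package deliberately does not do.
- The dummy baseline's pooled accuracy equals the pooled majority fraction;
  per-fold-averaged accuracies reported elsewhere can differ by a few
  points under imbalanced folds, and no attempt is made to reproduce that
  variant.
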