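---
title: "Simulating MEG-BMI training and its effect on phantom limb pain: models and methods"
author: "megbmi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating MEG-BMI training and its effect on phantom limb pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`megbmi` is a desk-scale re-implementation of an analysis chain used in
magnetoencephalography (MEG) brain–machine interface (BMI) studies of phantom
limb pain: decode attempted phantom-hand movements from sensor signals, train
patients in closed loop with decoders that either match, scramble, or replace
the phantom-hand representation, estimate cortical currents, quantify the
movement *discriminability* of the sensorimotor cortex, and relate its
training-induced change to changes in pain ratings. Because raw patient MEG
is not publicly available, the package ships a synthetic-data generator whose
statistical structure matches what the analysis assumes, so every stage of
the pipeline is testable end to end.

This vignette documents the models, the tunable parameters, and the design
decisions taken where the underlying methods left choices open.

## The synthetic recording model

A toy head model (`build_toy_head_model()`) places source vertices in two
clusters ("contra" and "ipsi" to the affected hand), labels the fraction of
vertices nearest each hemisphere centroid as the sensorimotor region of
interest (ROI), and places sensors on a surrounding sphere. The lead field is
a Gaussian distance-decay kernel, so sensor output is exactly linear in the
vertex currents — the one property of a physical forward model the analysis
relies on. The desk default is 32 sensors and 2 × 40 vertices;
`head_model_preset("study")` reproduces the published scale (4,004 dipoles,
126 ROI vertices per hemisphere, 84 selected channels out of 160). How the
84 channels were chosen was never specified in the source study; the
`select_channels()` stand-in takes the sensors nearest the ROI centroid.

The task schedule (`make_task_schedule()`) reproduces the offline paradigm:
a 50-s rest baseline, then instruction blocks (3-s fixation, 1-s instruction
word, two 1-s timing cues) each followed by `n_reps` execution cues spaced
5.5 s apart, with randomized class order; the default 10 instructions × 4
cues yields the study's 40 execution cues per movement class at 1,000 Hz.

Each execution cue adds a rectangular 0–500 ms source burst on the active
hemisphere's ROI:

* class templates are `amp * (onset_gain * u ± (d/2) * w)`, where `u` and `w`
  are fixed patient-specific spatial patterns whose sensor projections are
  orthonormal;
* `d` is the planted *discriminability*: the sensor-space separation of the
  two class templates is exactly `d * amp`, so one scalar controls how
  decodable the movement type is;
* the class-common component `onset_gain * u` (default gain 3) models the
  fact that movement-evoked fields are much larger than their
  class-discriminative part; it is what the move-vs-rest onset detector keys
  on and it cancels from every between-class contrast;
* the trial-averaged (signed) source is `amp * onset_gain * u` regardless of
  `d`, which implements the design constraint that mean current amplitude is
  identical across training conditions — only *pattern separability*
  changes, so any current–pain coupling would be an artefact.

Sensor noise is i.i.d. Gaussian. The default burst amplitude is expressed as
an effect size: `amp = 1.5 * noise_sd / sqrt(0.5 * rate)` makes the z-scored
class separation ≈ `1.5 d` independent of sampling rate. At the default
`d = 0.8` this puts sensor-space decoding near 65 %, the level reported for
pre-training phantom-hand decoding; the cohort preset uses effect scale 2 so
that *source-space* ROI decoding sits near 70 %, matching the reported
sensorimotor-current decoding level. Both anchors were fixed once, from the
published accuracy levels, before any acceptance measurement.

What the generator does **not** emulate: temporally autocorrelated (1/f,
alpha-band) MEG noise, head movement, the 200-Hz hardware anti-aliasing
filter, realistic dipole orientations or BEM physics, EMG leakage, and any
within-session non-stationarity. Passing tests therefore demonstrate that
the *analysis chain* behaves correctly under its own assumptions — not that
it would perform identically on real MEG.

## Preprocessing

Epochs are cut `[t_start, t_end)` around each execution cue (cue time mapped
to a sample by rounding down), averaged in 500-ms windows slid by 100 ms, and
z-scored per channel against the session's own initial 50-s rest baseline.
Two conventions required a decision:

* **Baseline statistics are computed on window means**, i.e. the same sliding
  windows are tiled across the baseline and their per-channel mean and s.d.
  define the z-transform. The alternative (raw-sample statistics) produces
  features whose scale shrinks with `sqrt(window length)` and makes kernel
  widths rate-dependent; window-mean statistics give unit-scale features at
  any sampling rate. The published wording does not distinguish the two.
* **Each session is normalized against its own baseline** (pre- and
  post-training sessions separately); whether the original analysis reused
  the pre-training baseline is not stated, and the tests verify that the two
  choices genuinely differ.

## Decoding

`nested_cv_accuracy()` implements the nested cross-validation estimator: the
outer 10-fold loop measures accuracy, and within each outer training set a
10×-repeated 10-fold inner CV scores every (cost, kernel width) combination
at every 500-ms window of the −500…1000 ms range. Each outer fold then
refits at its inner-CV winner and predicts its held-out trials, so
hyperparameters *and* the analysis window are always selected without any
influence from the trials they are judged on. The classifier is a
radial-basis-kernel soft-margin SVM; the working-set (SMO) solver is
implemented in C++ on precomputed per-window kernels so that the ~10^5 fits
of one session's nested CV run in seconds, and the test suite verifies its
decision values against the independent libsvm implementation in `e1071`.

Two estimator details matter:

* `classification_accuracy` pools outer-fold predictions at each fold's
  selected window. The window-resolved curve (`accuracy_by_window`) and its
  maximum are also reported, but the maximum over pooled window accuracies
  is optimistically biased for uninformative data (it selects over windows
  *after* seeing test predictions) and is kept as a diagnostic only. The
  fold-level estimator is unbiased at chance for permuted labels, which is
  what the reported ~51 % random-relabelling level reflects.
* The hyperparameter grid — cost ∈ {0.1, 1, 10} × kernel width
  {0.1, 1, 10}/p for p channels — was chosen for numerical conditioning on
  unit-scale z-features (wider grids change accuracy by < 1 % on this
  generator but inflate runtime ~5× through ill-conditioned corner
  combinations). Ties in inner accuracy resolve to the earliest window and
  the smallest combination index, deterministically.

The online decoder (`train_online_decoder()`) mirrors the two-part design:
a class decoder fit on all trials at the peak window, and a move-vs-rest
onset detector trained on windows covering ≥ 50 % of the 0–500 ms burst
(positives) versus baseline windows (negatives). Whether onset-detector
positives should be execution-cue- or instruction-locked is ambiguous in the
source description; execution-locked is the default, with
`onset_lock = "instruction"` exposed. The onset threshold is calibrated
post hoc (`calibrate_onset_threshold()`) as the smallest value silencing a
resting-state stream, reproducing the experimenters' manual adjustment.

The three decoder conditions are label policies: `true_labels` (phantom
decoder), `permuted_labels` (random decoder), and `other_effector`
(real-hand decoder, trained on the intact-hand session whose activation
lives in the opposite hemisphere).

## Closed-loop training

`run_closed_loop()` streams a simulated brain through the decoder for 10
minutes: intentions alternate in 5-s blocks with jittered onsets, every
100 ms the trailing 500-ms window is z-scored with the decoder's stored
baseline statistics, the onset detector gates the class decoder, and the
prosthesis state switches on detections. The class decision for a detected
onset is taken 400 ms later, when the trailing window covers the movement
burst — still causal, just delayed, as in practical onset-triggered
decoders. Plasticity is applied as a single end-of-session update
`final_d = d + delta_d[condition]`: the source study measured
discriminability only before and after training, so within-session dynamics
are deliberately not modelled (an exploratory exponential drift would be an
extrapolation, and is not implemented).

## Source inversion

`estimate_inverse_filter()` estimates per-vertex current variances by an
automatic-relevance-determination-style EM scheme: currents have independent
zero-mean Gaussian priors with variances `nu_v`, `nu_v` carries an
inverse-gamma hyperprior whose mode is `m0` times the baseline-estimated
variance and whose confidence is `gamma0` (defaults 100 and 10, the
published settings), and each iteration alternates the posterior current
estimate with the closed-form shrinkage update
`nu <- (S + gamma0 * nu0) / (T + gamma0)`. The penalized marginal
log-likelihood is non-decreasing across iterations (asserted per iteration
in the tests) and its relative change is the convergence criterion
(`tol = 1e-6`, `max_iter = 200` by default; the cohort analyses use
`tol = 1e-4`, which converges in ~50 iterations).

This is explicitly a functional stand-in for the original hierarchical
variational-Bayes source software, whose exact objective is not derivable
from the published description. Its contract is therefore written in terms
of testable limits: `gamma0 → ∞` must give the closed-form fixed-variance
Tikhonov (minimum-norm) filter; an identity lead field with negligible noise
must return the sensor signals; an isolated source in an over-determined
noiseless system must be localized at the least-squares solution. The
baseline current variance `nu0` is estimated by pushing the −1.5…−0.5 s
pre-cue signals through a fixed minimum-norm reference inverse; a flat prior
is available for the degenerate-limit tests. One scalar current per vertex
honours the orientation constraint by construction.

Estimated currents are windowed and z-scored against the filtered initial
50-s baseline by the same preprocessing code (the filter output is just a
recording whose channels are vertices), and the 0–500 ms post-cue window
mean is the per-trial analysis feature.

## Discriminability maps and outcomes

`vertex_f_map()` computes the classic one-way ANOVA `F = MS_between /
MS_within` per vertex on those window means (verified against hand
sums-of-squares, against `aov()`, and against the two-class identity
`F = t²`). Zero within-class variance yields `+Inf` with an explicit
degeneracy flag. ROI decoding (`roi_decoding_accuracy()`) restricts the
z-scored currents to one hemisphere's sensorimotor vertices and reuses the
nested-CV machinery unchanged. `compute_outcomes()` assembles, per
patient × condition, the post-minus-pre changes: ΔF per vertex, Δaccuracy
for the contralateral and ipsilateral ROI, Δcurrent (trial-mean z-current,
contralateral ROI average), ΔVAS and the ΔSF-MPQ2 scores.

## The plasticity and pain model

The source study reports no generative model for either; the generator uses
the simplest structure consistent with the reported analyses:

* **Plasticity**: `d_post = d_pre + delta_d[condition] + jitter`, with
  defaults `d_pre = 0.8`, `delta_d = (+0.5, 0, −0.5)` for the
  phantom/random/real-hand decoders and a per-patient jitter s.d. of 0.15
  (floored at `d = 0`). The deterministic condition effect reproduces the
  reported ordering of accuracy changes; the jitter produces the
  inter-patient scatter visible in the published accuracy–pain scatter
  plots.
* **Pain**: ΔVAS = `beta_pain` × Δd + Gaussian noise, with
  `beta_pain = 15` VAS units per unit discriminability (so the phantom
  condition shifts VAS by ≈ +7.5, matching the reported 38.2 → 45.8 change)
  and noise s.d. 5. Baseline VAS is drawn near 38 and all scores are clipped
  to 0–100. Of the four SF-MPQ2 subscores only the continuous-pain subscore
  carries a coupling (`beta_mpq2 = 6`); the others are pure noise, and the
  total is the sum — mirroring the finding that only continuous pain varied
  by condition. Items within subscores are not modelled; subscores are
  opaque sums.

Because measured Δaccuracy contains decoding-estimation noise, the
population correlation between Δaccuracy and ΔVAS is not `beta_pain`-free to
set directly. `calibrate_pain_noise()` measures the accuracy response slope
and residual s.d. by Monte-Carlo, then solves the linear-model identity for
the pain-noise s.d. that yields a requested population correlation (the
published R = 0.66 at n = 30 serves as the calibration anchor). The
attainable maximum correlation is reported, and an unattainable request is
an error rather than a silent shortfall.

## Problem sizes

Single-session analyses (and the chance-level acceptance computation) run at
the full design: 1,000 Hz, 32 sensors, 40 trials per class, 10-fold outer ×
10×10 inner CV over 11 windows — about 10⁵ SVM fits per session, a few
seconds with the C++ solver. Cohort-level Monte-Carlo studies (correlation
recovery over 100 cohorts, condition-ordering checks over 20) use
`cohort_session_params()`: 100 Hz, 16 sensors, 2 × 20 vertices, 40 trials
per class, and the `"fast"` decode profile (the single informative 0–500 ms
window, fixed hyperparameters, 5-fold CV — the nested selection degenerates
gracefully when there is nothing to select). These sizes are the package's
chosen simulation design for keeping a 100-cohort study in minutes on one
core; all structural parameters (trial counts, baseline length, cue timing)
stay at the study's values.

## Known limitations

* The sensor-noise model is white; real MEG chance levels and window
  correlations will differ in detail (the window-resolved diagnostic curve
  is more correlated across neighbouring windows on real data).
* The n = 30 correlation analyses pool 3 conditions × 10 patients as
  independent pairs, reproducing the published analysis choice; a
  mixed-effects treatment of the repeated measures is deliberately out of
  scope.
* Group maps assume identity registration across simulated patients (all
  share one toy head model); per-patient anatomy and surface registration
  are not modelled.
* The inverse is a documented stand-in: agreement with the original source
  software can only be claimed in the tested limits, not in general.
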