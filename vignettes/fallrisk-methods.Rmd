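---
title: "Methods: synthetic wearable-sensor fall-risk pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic wearable-sensor fall-risk pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`fallrisk` implements an end-to-end fall-risk assessment pipeline for stroke
survivors instrumented with eight inertial sensors (both feet, shanks and
thighs, pelvis, thorax) sampled at 60 Hz while performing a ten-task clinical
battery: quiet standing with eyes open and closed, the Timed Up and Go (TUG),
a 10 m walk, and a five-repetition sit-to-stand (STS), each performed
single-task and with a concurrent counting-backward (dual) task. From each
recording the package extracts a fixed 92-feature pool — 42 single-task motion
features, the same 42 recomputed on the dual-task trials (`Dual_` prefix), and
8 clinical/demographic features — and classifies subjects as fallers versus
non-fallers with forward feature selection evaluated under
leave-one-subject-out (LOSO) cross-validation.

Because clinical recordings cannot ship with the package, a synthetic-data
generator produces cohorts with the same structure and known ground truth.
Every downstream stage (filtering, segmentation, features, modeling) is
testable against that truth.

# The synthetic generator

Signals are scripted motifs plus stochastic components, so every event a
detector must find has one unambiguous annotated time:

* **Postural transitions** (sit-to-stand, turns, stand-to-sit) are Gaussian
  angular-velocity lobes whose 10 %-of-peak crossings are placed exactly at
  the scripted onset/offset: a lobe spanning $[a, b]$ has its center at
  $(a+b)/2$ and $\sigma = (b-a) / (2\sqrt{2\ln 10})$. Nominal amplitudes:
  thigh 85 deg/s, thorax 45, pelvis 30 (STS); thorax pitch 55 / −50 and yaw
  70 / 60 deg/s (TUG).
* **Gait events** are narrow symmetric Gaussian bumps
  ($\sigma = 25$ ms) added to the foot and shank accelerations: heel strikes
  with amplitudes 1.5 / 2.5 m/s² on the anterior/vertical axes, toe-offs at
  one third of that, feet scaled by 1.2 relative to shanks. A symmetric bump
  was chosen deliberately over an asymmetric decaying transient: under the
  zero-phase low-pass used everywhere downstream, a symmetric bump's peak
  stays at the annotated truth time, while an asymmetric transient's peak
  shifts, which would make the ±50 ms / ±1-sample recovery contracts
  ill-defined.
* **Stride timing**: i.i.d. normal stride times (nominal 1.1 s, SD 0.04 s,
  truncated positive), constant 1.15 m stride length, swing fraction 0.35,
  feet offset by half a stride.
* **Postural sway** is white noise shaped by a 1 Hz second-order low-pass,
  rescaled per axis to an exact target standard deviation (thorax base
  0.030/0.025/0.015 m/s² per axis; pelvis ×0.8, thighs ×0.5; eyes closed
  ×1.4).
* **Sensor noise** is additive white noise (default SD 0.02 m/s² or deg/s)
  on every channel.

Group differences are multiplicative effect sizes (`effect_profile()`):
fallers sway ×1.5, walk at ×0.8 speed, transition ×1.3 slower, and pay a
×1.2 dual-task cost versus ×1.05 for non-fallers; a per-subject latent
mobility factor in (0, 1] plus a per-trial lognormal performance jitter
(sway 15 % CV, transitions 7 %, stride time 5 %, matching typical
test–retest variability) add within-group heterogeneity, so the groups are
separable but overlapping rather than trivially split. Clinical tables
(gender, age, height, weight, five questionnaire items, comorbidity count,
short FES-I score in 7–28) are drawn from group-level summary statistics.

The generator emulates the *structure and effect directions* of such a study,
not real biomechanics: there are no orientation drifts, no magnetometer or
gravity artifacts, no double support modeling beyond the swing fraction, and
trial-to-trial variability is purely parametric. Conclusions about real
sensors should not be drawn from it; its purpose is verifiable ground truth.

# Preprocessing

All channels pass through a 4th-order Butterworth low-pass at 5 Hz
(`filter_spec()`), applied forward and backward so event timing is not
delayed. The series is reflect-padded about its end points (pad length
`max(3*order, fs)` samples, capped at `n − 1`) to suppress edge transients.
The filter is implemented with cached `signal::butter` coefficients applied
via the C-level `stats::filter` convolution/recursive paths; this is
numerically identical to `signal::filter` and fast enough for
simulation-heavy test suites. With two passes the design cut-off is the −6 dB
point of the effective response; the single-pass gain at the cut-off is
1/√2 (checked in the tests against the closed form).

# Segmentation

* **Gait events** (`detect_gait_events()`): candidate peaks of the filtered
  resultant acceleration above an adaptive `median + 3·MAD` threshold; heel
  strikes are candidates at ≥ 50 % of the tallest candidate, thinned to a
  minimum spacing of 0.4 × the stride prior; each toe-off is the tallest
  remaining candidate in a window (0.10, 0.55) × median inter-HS interval
  before the following heel strike. The window is stride-scaled rather than
  fixed in seconds so that slow (faller × dual-task) gait, whose swing time
  can exceed 0.6 s, keeps its toe-offs inside the window. Everything is
  scale-free: amplitude rescaling does not change detected times.
* **TUG phases** (`segment_tug()`): thorax pitch lobes give the sit-to-stand
  onset (t1) and task end (t6); the two tallest yaw lobes give the turn (t3)
  and turn-and-sit (t5) onsets; walk initiations (t2, t4) are the first foot
  impact after the preceding lobe's offset. Invalid segmentations return
  named diagnostics and a `valid = FALSE` flag; feature extraction refuses
  them rather than guessing.
* **STS cycles** (`detect_sts_cycles()`): convex lobes of the filtered thigh
  angular velocity, paired sequentially (up, down). Here the lobe threshold
  is 25 % of the trial maximum rather than `median + MAD`: transition lobes
  occupy most of an STS trial, which inflates median/MAD-type thresholds,
  whereas sparse gait impacts do not. Lobe boundaries are 10 %-of-peak
  crossings with sub-sample linear interpolation. A count that disagrees
  with the expected five repetitions is flagged, never silently corrected.

# Features and modeling

`feature_catalogue()` enumerates the 92 features with per-feature sensor
requirements (data, not code — `available_features()` filters it for the
sensor-configuration search). `assemble_feature_table()` produces the
subjects × 92 table and fails loudly on any extraction problem; missing
values are never imputed.

`forward_select()` wraps greedy forward selection around LOSO evaluation:
step 1 keeps the best single feature, each later step the best extension;
ties break to higher accuracy, then higher sensitivity, then the earlier
catalogue position; selection stops when no candidate strictly improves
accuracy, at `max_features`, or at perfect accuracy. The default `"pooled"`
mode scores candidate sets by their LOSO accuracy over all subjects and
yields one global trajectory — the classical wrapper protocol, whose
reported accuracy is optimistically biased because selection saw every
subject. `"nested"` mode reruns selection inside every training fold and
aggregates only the hold-out predictions, giving an honest generalization
estimate at ~n× the cost. Both are provided; results from pooled mode should
be read as descriptive, not as out-of-sample performance.

Backends are the field-standard implementations: `randomForest` (default
`ntree = 200`; out-of-bag error is long stable at that size for cohorts of a
few dozen subjects, and forward selection at 21 subjects runs thousands of
fits), `e1071::svm` (linear kernel, cost 1) and `glmnet` ridge logistic
regression (`alpha = 0`, `lambda = 1/n`; a ridge rather than unpenalized fit
because p can exceed n during selection). Standardization uses training-fold
statistics only and is mandatory for the margin/linear models. The default
`max_features = 5` bounds the selection cost; informative models in this
setting carry 2–5 features, and the cap is an ordinary argument when more
are wanted.

Fallers are the positive class: sensitivity is the true-positive rate on
fallers, specificity the true-negative rate on non-fallers, and
`accuracy = (sens·n_fallers + spec·n_nonfallers) / n` (an identity the tests
verify). Metrics for an absent class are `NA`, never 0.

# Problem sizes and runtime

The default cohort is 11 fallers + 10 non-fallers × 10 trials at 60 Hz
(~30 s balance trials, ~10–25 s task trials). On one CPU core, cohort
generation takes ~7 s, feature extraction ~6 s, and one full 92-candidate
forward-selection sweep ~10–30 s depending on the classifier. The
sensor-configuration search is exhaustive over 7 configurations × 175 test
subsets (sizes 1–3); with the random forest this is hours of compute, so use
the logistic spec for wide searches.

# Limitations

* Synthetic effect sizes are set a priori; classification accuracies on
  synthetic cohorts say nothing about clinical performance.
* Pooled-mode selection accuracy is biased upward by design (see above).
* The generator's dual-task cost is a uniform multiplier; real dual-task
  interference is task-specific.
* Segmentation heuristics are tuned to the motif family the generator
  produces; real IMU data would require revalidation of thresholds and
  windows.
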