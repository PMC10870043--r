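---
title: "Tangent-space decoding of surface EMG hand gestures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tangent-space decoding of surface EMG hand gestures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgesture)
```

## The decoding problem

Surface electromyography (EMG) records the electrical activity of muscles
through skin electrodes. Different hand and wrist gestures recruit different
forearm muscles, so a multichannel forearm array sees each gesture as a
distinct *spatial pattern* of activity. `emgesture` implements a complete
decoding chain for this setting: an 8-channel array sampled at 2000 Hz, a
cue-based protocol in which each trial presents every gesture once (3 s of
rest, then 3 s of instructed gesture), and a ten-gesture vocabulary
(idle, left, right, up, down, fist, spread, index, ring, pointing).

The key modelling idea is that over a short window the EMG is approximately
a zero-mean multichannel process whose discriminative content lies in its
second-order structure. The spatial covariance matrix (SCM) of a window
$X \in \mathbb{R}^{C \times N}$,

$$\mathrm{SCM} = \frac{X X^\top}{N - 1},$$

is symmetric positive-definite (SPD) and therefore a point on the SPD
manifold. Classifying gestures becomes classifying points on that manifold.

## Pipeline

### Filtering

Two Butterworth stages precede everything else:

* **Powerline removal.** A cascade of band-stop (notch) stages at the mains
  fundamental (60 Hz) and each harmonic $k \cdot 60$ Hz, with stop edges
  $\pm 8$ Hz around each centre. Harmonics are notched as long as the stop
  band lies below the upper edge of the EMG band (450 Hz) — at 2000 Hz
  that is $k = 1,\dots,7$ — since anything higher is removed by the
  band-pass anyway. A tone cannot be removed by a pass band, so stop-band
  stages are the only reading of "removing powerline noise" that does what
  it says.
* **EMG band-pass**, 20–450 Hz: removes motion-artifact drift below 20 Hz
  and out-of-band noise above 450 Hz.

Both stages are order-4 Butterworth *designs*; a band transform doubles the
pole count, and the default zero-phase (forward–backward) application
squares the magnitude response. The `filter_spec` objects record the
resulting effective order rather than hiding it. Zero-phase filtering is the
default because offline analysis benefits from exact time alignment between
windows and cue labels; a causal single-pass mode (`zero_phase = FALSE`)
exists for streaming use, where group delay is the price of causality.

The designed responses are verifiable against the closed-form bilinear-warped
Butterworth magnitude exposed as `butterworth_gain()`; the test suite holds
every probe frequency to within 0.5 dB of that analytic curve.

### Segmentation

Filtered recordings are cut into 300 ms windows (600 samples at 2000 Hz)
with 96 % overlap, i.e. a hop of $\mathrm{round}(600 \times 0.04) = 24$
samples. Windows are restricted to each cue's label window (default 0–3 s
after onset, the instructed-gesture period), so a 3 s cue yields
$\lfloor (6000 - 600)/24 \rfloor + 1 = 226$ windows and no window ever
straddles a rest/gesture boundary. Boundary-straddling windows would carry
mixed-class samples; excluding them keeps the training labels clean, at the
cost of discarding a fraction of a second of data per cue.

### Riemannian features

With SCMs as points on the SPD manifold, the package uses the
affine-invariant Riemannian metric (AIRM),
$$\delta(P, Q) = \left\lVert \log\!\left(P^{-1/2} Q P^{-1/2}\right)\right\rVert_F
  = \sqrt{\textstyle\sum_i \log^2 \lambda_i(P^{-1}Q)},$$
which is invariant to any invertible linear re-mixing of channels — a
useful property when electrode placement and inter-channel crosstalk vary.

Training SCMs are summarized by their Fréchet mean (the manifold's centre
of mass), computed by the standard fixed-point iteration
$$M \leftarrow M^{1/2} \exp\!\Big(\nu\, \overline{\log\!\big(M^{-1/2} P_i M^{-1/2}\big)}\Big) M^{1/2},$$
initialized at the arithmetic mean and stopped when the Frobenius norm of
the mean log (the Riemannian gradient) drops below $10^{-8}$. The step
size $\nu$ starts at 1 and adapts to progress: $\nu \cdot \lVert G \rVert$
is tracked against the best value seen, $\nu$ shrinking gently
($\times 0.95$) while it improves and halving when it does not. On large
sets of widely spread covariances the unit-step iteration oscillates or
converges only linearly, and this adaptation restores steady contraction
(typically under 20 iterations on full-scale training folds). The
iteration cap is 200; hitting it raises an error that carries the final
gradient norm rather than silently returning an unconverged mean.

Each SCM $P$ is then mapped to the tangent space at the training mean $M$:
$$S = \log\!\left(M^{-1/2} P M^{-1/2}\right),$$
half-vectorized (upper triangle, row-major) with off-diagonal entries
weighted by $\sqrt{2}$. That weighting makes the map an isometry at the
reference — the Euclidean norm of a feature vector equals
$\delta(M, P)$ — which is both a clean geometric property and a direct
numerical test. For 8 channels the feature dimension is
$8 \cdot 9 / 2 = 36$.

One *global* Fréchet mean is computed from the training windows of each
fold and reused to map that fold's training and test windows; per-class
means are not used. A small diagonal shrinkage
($10^{-8} \times \mathrm{trace}/C$) keeps rank-deficient windows strictly
positive-definite without materially moving well-conditioned SCMs.

### Classification

Tangent vectors are ordinary Euclidean features, so any standard classifier
applies. The shipped default is an RBF-kernel SVM with cost 1.09 and
$\gamma = 1/72$, one-vs-one for the multiclass decision, and *no* feature
scaling between tangent mapping and classifier — the tangent construction
already whitens relative to the reference (a config switch, should a user
want scaling). `grid_search_svm()` tunes cost and $\gamma$ over a log grid
($2^{-5..5} \times 2^{-10..2}$) with stratified inner folds and
deterministic tie-breaking (smallest cost, then smallest $\gamma$).

Thirteen classifier families can be compared on identical folds and
identical per-fold tangent features (`compare_classifiers()`): SVM, kNN,
logistic regression, extra trees, random forest, LDA, leaf-wise histogram
gradient boosting, Gaussian naive Bayes, QDA, ridge-on-indicators,
depth-wise gradient boosting, a decision tree, and SAMME AdaBoost over
stumps. Engines are the field-standard R implementations (e1071/libsvm,
class, nnet, ranger, MASS, xgboost, rpart); the ridge classifier and the
SAMME booster are implemented in-package (closed-form ridge on one-hot
targets with argmax decision; stump-based SAMME), and the leaf-wise
booster is xgboost's histogram method with loss-guided growth. A family
whose fit fails on a given dataset is reported as `missing` in the
comparison table, never dropped.

### Evaluation protocols

* **Leave-one-trial-out** — each trial held out once; the Fréchet mean and
  the classifier are refit per fold from the remaining trials only. The
  trial, not the window, is the independent unit, because the 96 % overlap
  makes neighbouring windows nearly identical; splitting windows at random
  would leak test information into training.
* **Train-first-test-rest** — fit once on trial 0, score each later trial
  separately. This is the long-term, train-once protocol: with 11 trials
  it produces 10 test accuracies tracking how a single short calibration
  holds up over repeated use.

Accuracy is counted per window by default (the label stream a continuous
controller consumes); `score = "cue_vote"` aggregates windows by majority
vote within each cue for per-event accuracy.

## Signal-to-noise evaluation

`snr_db()` quantifies recording quality around each cue:
$\mathrm{SNR} = 10 \log_{10}(P_\text{signal}/P_\text{noise})$ per channel
and cue, with power taken as the mean-removed mean square (the variance) in
two cue-relative windows — noise from $-3$ to $-1$ s (rest, stopping 1 s
short of the cue to avoid anticipatory activity) and signal from $+1$ to
$+3$ s (steady gesture, skipping the reaction onset). Variance as the power
definition makes DC offsets irrelevant, and the ratio cancels any overall
gain, so the measure is scale-invariant. Values are pooled over all
channel × gesture pairs into a single mean ± SD, the way a single figure is
quoted for a whole device.

## Statistical comparison

`paired_comparison()` encodes a common biosignal-study decision rule: a
Kolmogorov–Smirnov-type normality check on the paired differences gates
between a paired *t*-test (normality not rejected at $\alpha = 0.05$) and
the Wilcoxon signed-rank test. Because the mean and SD of the differences
are estimated from the same sample, the naive KS critical values would be
anti-conservative; the gate therefore uses the Lilliefors correction (with
a Shapiro–Wilk fallback below $n = 5$, where the Lilliefors table does not
apply). All-zero differences are reported as a degenerate case instead of
a test result. The suite verifies the combined procedure holds its nominal
type-I error under a Gaussian null and that null *p*-values are
approximately uniform.

## The synthetic data generator

No public recordings accompany this problem setting, so the package ships
a generator (`generate_recording()`) whose defaults *are* the study
conditions: 8 channels, 2000 Hz, ten gestures, 3 s rest + 3 s gesture per
cue, one presentation of each gesture per trial in seeded random order,
3 trials per session.

Each gesture's carrier is band-limited (20–450 Hz) Gaussian noise,
amplitude-modulated per channel and linearly mixed across channels:
$$x_c(t) = a_{g,c} \, [B_g\, n(t)]_c + \text{powerline}(t) + e(t),$$
with $a_g = a_0 \exp(s\, z_g)$ and $B_g = \exp(\tfrac{s}{2} S_g)$, where
$z_g$, $S_g$ are fixed seeded patterns per gesture, $a_0 = 30\ \mu V$ RMS,
and $s$ is the `separation` parameter. The idle/rest state uses the flat
pattern $z = -0.7$ (no mixing), so resting muscle tone sits well below
active gestures at the default separation while every class collapses to
the *same* covariance at $s = 0$ — the chance-level control condition.
Baseline white noise is 5 µV RMS and powerline contamination defaults to
20 µV at 60 Hz with harmonics rolling off as $1/k$; activation peaks are
of order 100 µV at the default $s = 2$, all in the physiological
surface-EMG range (values are configuration, not claims about any
particular device). The band-shaping filter's exact noise gain is computed
from its impulse response so carriers stay unit-variance, which keeps the
ground truth analytic:
$$\Sigma_g = D_{a_g} B_g B_g^\top D_{a_g} + \sigma_b^2 I .$$
These theoretical covariances are returned with every session and the
suite checks that empirical window SCMs converge to them (within 10 %
relative Frobenius error on 3 s windows, 3 % at 30 s).

A Gaussian carrier is the honest choice here, not a limitation hidden in
defaults: the pipeline consumes only second-order structure, so Gaussian
surrogates exercise every stage while keeping ground truth exact. What the
generator does **not** emulate — motor-unit action potentials and their
non-Gaussian amplitude statistics, fatigue drift, electrode lift and
motion artifacts, inter-subject variability — is exactly what passing
tests on synthetic data cannot certify about real recordings. Synthetic
recovery shows the chain is correct and leak-free, not that any particular
accuracy will be reached on a given subject.

## Numerical and design choices

* **Windows within a cue are dependent** (96 % overlap), so wherever a
  binomial reference interval is needed (the chance-level check), the cue —
  not the window — is used as the exchangeable unit. Under identical class
  covariances predictions are independent of the true label, so expected
  accuracy is exactly $1/K$ either way; only the variance changes.
* **Determinism.** Every stochastic step takes an explicit seed: the
  generator reproduces sessions bit-for-bit; per-fold fits are seeded
  `seed + fold`, making each fold's fit a pure function of its training
  data — the basis of the refit-equality leakage test.
* **Problem sizes in the test suite.** Full-scale sessions (10 gestures,
  3 trials, 226 windows per cue; several seeds) are used for the headline
  recovery checks; smaller 4-gesture, reduced-overlap sessions are used
  for interface-level tests where scale adds nothing to the property under
  test.
* **Degenerate inputs** get named errors (`emg_*` condition classes):
  ragged channels, non-finite samples, non-increasing cue onsets, stop
  bands crossing Nyquist, non-PD matrices, single-class training sets,
  windows outside the recording, zero noise power, all-zero paired
  differences.
* **File formats.** A text pair (CSV channels + JSON sidecar, fixed
  6-decimal precision, round-trip error $\le 5 \times 10^{-7}$) for
  fixtures and documentation, and an RDS binary archive (lossless) for
  full sessions. Units are microvolts throughout; nothing ever rescales
  silently.

## Worked example

```{r example, eval = FALSE}
library(emgesture)

sess <- generate_recording(synth_config(seed = 1))
rec  <- preprocess_recording(sess$recording)
seg  <- segment_windows(rec, sess$cues)

rpt <- cross_validate_trials(seg, classifier_spec("SVM"), seed = 1)
glance(rpt)
autoplot(rpt)          # confusion heat map

tab <- compare_classifiers(seg, protocol = "leave_one_trial_out", seed = 1)
autoplot(tab)

snr <- snr_db(sess$recording, sess$cues)
glance(snr)
```

## Known limitations

* The tangent-space reference is a single global mean; per-class means or
  class-recentring variants are not implemented.
* No domain adaptation: fatigue- or session-drift compensation is out of
  scope, as is any online/incremental update of a fitted pipeline.
* The causal filtering mode changes window alignment relative to the
  zero-phase default; models should be trained and applied in the same
  mode.
* Real-device concerns — wireless acquisition, artifact rejection beyond
  the stated filters, electrode impedance — are outside the package.
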