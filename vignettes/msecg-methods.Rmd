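---
title: "Detecting metabolic syndrome from ECG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting metabolic syndrome from ECG: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msecg)
```

# Overview

`msecg` implements an automatic detection pipeline for metabolic syndrome
(MS) from multi-lead electrocardiograms. The pipeline has five stages:

1. **QRS delineation** — Pan–Tompkins R-peak detection, a
   derivative-inversion search for the S trough, and a *time-flip* variant
   of the same search for the Q trough;
2. **feature extraction** — 30 per-record statistics built from QRS
   intervals, amplitude ratios, R amplitudes and the frontal-plane cardiac
   axis on leads I and aVF;
3. **classification** — an RBF-kernel SVM and a RobustBoost tree ensemble
   on the feature table, and a small convolutional network on raw windowed
   signal segments;
4. **evaluation** — subject-wise stratified k-fold cross-validation
   (k = 10) with the seven standard confusion-matrix metrics, plus a
   repeated-CV accuracy-distribution protocol;
5. **statistics** — a Kolmogorov–Smirnov normality screen, per-feature
   Mann–Whitney tests by OGTT stage, point-biserial correlation with group
   membership, PCA loading-based feature relevance, and Bland–Altman
   agreement analysis for validating the delineator.

The clinical recordings this design targets (an oral glucose tolerance
test cohort of 15 MS and 10 control males, 12-lead, 1 kHz, five stages)
are not publicly deposited, so the package ships a seeded synthetic
cohort generator that emulates the study design and provides exact
beat-level ground truth. Every downstream stage is tested against that
ground truth.

# The synthetic cohort generator

## Beat model

Each beat is a sum of Gaussian deflections: Q and S troughs flanking a
dominant R peak, plus optional low-amplitude P and T waves (default on,
so the trough searches must discriminate them). The single-beat kernel is
evaluated numerically at the requested sampling rate and its extrema are
located numerically — those extremum offsets, not the nominal Gaussian
centers, are the ground-truth annotations, so delineation accuracy is
checkable to the sample.

Beat-to-beat physiologic variability comes from four seeded sources, each
with an overridable per-subject parameter:

| parameter | default | meaning |
|---|---|---|
| `rr_cv` | 0.05 | coefficient of variation of log-normal RR intervals |
| `amp_jitter_sd` | 0.02 | per-beat multiplicative amplitude jitter |
| `qs_jitter_sd_ms` | 2 ms | per-beat Q/S timing jitter (kernel variants) |
| `frac_jitter` | 0.05 | per-beat relative Q/S depth jitter |
| `axis_jitter_sd` | 3° | per-beat (respiratory) axis jitter |
| `stage_jitter_sd` | 0.005 | per-record heart-rate jitter |

Setting all of them to zero yields a zero-dispersion record — identical,
equally spaced beats — for which every variance feature is exactly zero.

## Leads and the cardiac axis

A common source waveform is projected onto the frontal plane: lead I with
gain $\cos\theta$ and aVF with gain $\sin\theta$, where $\theta$ is the
per-beat axis angle. An optional 12-lead mode adds the remaining limb
leads by the standard lead angles and six pseudo-precordial leads with
fixed gains and small independent noise; only leads I and aVF carry
ground-truth structure.

## Group effects

MS subjects differ from controls through four programmed contrasts
(`group_effects()`): an axis shift (default −30°, a leftward deviation —
the direction produced by left-ventricular hypertrophy, the mechanism the
clinical literature associates with MS axis deviation), an RR-variability
scale (default 1.8), a QRS-width scale (default 1.15) and an R-amplitude
scale (default 1.25). Controls draw their axis from N(40°, 10°). The
sizes were chosen once to make the groups separable at study scale while
keeping per-subject overlap — a few subjects in every cohort are
genuinely ambiguous — and are not clinical estimates: the source study
reports no quantitative effect sizes. Neutral effects (`null_effects()`)
give exchangeable groups for calibration experiments.

## Noise

`add_noise()` adds Gaussian white noise, band-limited (< 1 Hz) baseline
wander, or 30–150 Hz electromyographic bursts, scaled per lead so the
realized SNR equals the request exactly (the scale uses the empirical
power of the generated noise). 24 dB corresponds to the noise-stress
recordings used to validate detectors of this family.

## What the generator does not emulate

Real 12-lead morphology (notched QRS, ST segments, U waves), arrhythmia,
electrode motion with signal dropout, inter-lead timing skew, and any
glucose dynamics across OGTT stages beyond a small deterministic
heart-rate modulation. Passing tests therefore demonstrate correctness of
the algorithms under controlled conditions, not clinical performance.

# Delineation

`detect_r_peaks()` follows the classic recipe: 5–15 Hz zero-phase
Butterworth band-pass, five-point derivative, squaring, 150 ms centered
moving-window integration, adaptive dual thresholds with search-back, and
a 200 ms refractory period. Accepted candidates are snapped first to the
band-passed QRS apex (±75 ms; robust to shoulder maxima of the integrated
signal) and then to the raw-signal apex (±50 ms). The detector assumes an
upright R wave in the analyzed lead.

`locate_s_peaks()` finds, for each R peak, the nearest local minimum of
the raw signal — a sign inversion of the first difference — after the
peak and within a 120 ms window (the upper range of normal QRS duration,
with margin). `locate_q_peaks()` is *exactly* the same search run on the
time-flipped signal at the mirrored R positions, mapped back through
$q = N + 1 - s'$; the identity is asserted bit-exactly in the tests.
The S search runs after R and the mirrored Q search therefore lands
before R; a trough on the wrong side, or no inversion inside the window
(e.g. a monotone tail at the record end), marks the beat failed with an
`NA` sentinel — failed beats are excluded from downstream statistics, not
interpolated.

A lead whose net QRS deflection is negative (aVF whenever the axis dips
below zero) cannot satisfy a literal trough search; with
`auto_invert = TRUE` the search runs on the baseline-mirrored signal
while amplitudes keep their true sign. The cohort feature pipeline
enables this for aVF and reuses lead I's R peaks across leads, because
the axis features need beat-aligned annotations.

# The feature set

Thirty features per record, ordered canonically (`feature_names()`): per
lead, mean and variance of the RR, RS, QS and QR intervals (ms, ms²), of
the signed R/Q and R/S amplitude ratios, and of the R amplitude (mV);
plus mean and variance of the per-beat frontal-plane axis, a two-lead
composite that appears once. Conventions:

* amplitudes are read from the raw signal at the annotated indices,
  baseline-corrected by the per-lead median;
* the per-beat axis is `atan2` of the net QRS amplitudes (signed sum of
  Q, R, S amplitudes) of both leads, *sampled at lead I's annotation
  instants* — the net QRS vector is simultaneous across leads, and this
  keeps the axis defined even when one lead is electrically silent;
* axis statistics are arithmetic (not circular), valid because
  physiological axes stay far from ±180°;
* every variance uses the n−1 divisor;
* beats whose |Q| or |S| amplitude falls below 1% of that beat's |R| are
  excluded from the ratio features only (near-zero denominators);
* signed ratios are the default; absolute ratios are available by flag.

# Classifiers

**SVM.** RBF kernel; features z-scored with training-fold statistics
only; kernel scale from the median heuristic; box constraint 1.

**RobustBoost.** A boost-by-majority approximation designed to tolerate
label noise, implemented here from its defining schedule: each example
carries a margin $m_i$; weights are
$w_i = \exp(-(m_i - \mu(t))^2 / 2\sigma(t)^2)$ with
$\sigma(t)^2 = (\sigma_f^2 + 1)e^{2(1-t)} - 1$ and
$\mu(t) = (\theta - 2\rho)e^{1-t} + 2\rho$, where $\rho$ solves the
error-goal condition at $t = 0$ ($\sigma_f = 0.1$, margin goal
$\theta = 0$, error goal default 0.1). Each cycle fits a depth-limited
`rpart` tree to the weighted sample, then takes a joint step
$(\Delta t, \alpha)$: $\alpha$ solves the zero-edge equation at the
advanced time (which is the minimizer of the mean potential
$1 - \Phi((m - \mu)/\sigma)$) and is capped at 0.3 per cycle; $\Delta t$
is the largest value keeping the mean potential non-increasing, found by
bisection. Training self-terminates when $t$ reaches 1 or no admissible
step remains.

Two time-stepping modes are exposed because the discretization genuinely
matters:

* `cycle_paced` (default) additionally caps $\Delta t$ at `2/n_cycles`,
  so a run builds an ensemble on the order of the cycle budget — the
  regime in which this classifier is reported to perform best (about 100
  cycles);
* `adaptive` takes the largest admissible step. Runs on easy data then
  finish in a handful of cycles (the error goal is secured), and on
  label-noisy data the time variable stalls before the endgame — that
  stall is precisely the give-up-on-unfittable-examples behavior that
  makes the algorithm robust, and the mode under which the label-noise
  property is tested.

Base trees honor a weak-learner contract (minimum leaf size of 5% of the
sample): boosting robustness presupposes learners that cannot memorize
isolated, possibly mislabelled points. At very small n (a few dozen
rows), no tree ensemble of any flavor is robust to 20% label flips —
the trees either memorize the flips or underfit — so the robustness
property is exercised at n = 1000 in 10 dimensions with stumps and the
error goal set near the expected noise level, which is how the error-goal
parameter is meant to be used. A plain AdaBoost fallback sits behind the
same interface (`method = "ada"`).

**CNN.** The network is implemented directly in R with im2col gathers
and BLAS matrix products: input → conv (100 filters, 5×5, same padding)
→ ReLU → 2×2 max-pool → conv (100 filters, 8×8) → ReLU → 2×2 max-pool →
fully-connected → softmax → 2-class output (10 layers in this counting
convention). Training uses SGD with momentum 0.9, initial learning rate
1e-4 multiplied by 0.1 every 8 epochs, L2 regularization 4e-4, at most 5
epochs, mini-batches of 30. Windows enter as (n_leads × window length)
single-channel images, zero-centered and scaled per lead by training-set
statistics. With 2-lead input the kernels overhang the lead dimension;
under same-padding the kernel rows that can never overlap the input are
inert — they exist as parameters but receive no gradient — and pooling
blocks are clipped at the boundaries. Weight initialization is seeded
He-style; the forward and backward passes are verified against a
nested-loop convolution oracle and finite-difference gradients in the
test suite. Subject-wise isolation is asserted inside `train_cnn()`:
any overlap between training windows and declared test subjects is a
hard error. Per-subject labels aggregate window predictions by majority
vote, with ties to the positive class.

# Evaluation protocol

Folding is always at subject level and stratified by default — with a
15/10 class split and k = 10, unstratified folds regularly contain a
single class. Per-fold metrics come from held-out predictions only; the
pooled report is the per-metric mean ± sd across folds (fold-averaged,
matching the protocol; pooled-count metrics are also reported for
transparency). Metrics with zero denominators are flagged `NA`, never
silently zero. The positive class is MS throughout. Undefined feature
cells (e.g. ratio features of a silent lead) are imputed with
training-fold medians. `repeated_cv()` re-randomizes both fold assignment
and classifier seeding per repetition (500 repetitions with k = 10 in
the reference protocol) and returns the full accuracy distribution with
binned relative frequencies.

# Statistical battery

The normality screen is a plain one-sample KS test of the z-scored data
against the standard normal — estimating the moments from the sample
inflates the p-value (the Lilliefors effect), so the screen is
conservative; a Lilliefors-corrected variant is available. The
Mann–Whitney test uses exact enumeration when tie-free with
$n_a + n_b \le 12$ and the tie-corrected normal approximation otherwise;
it is verified against an exhaustive permutation oracle. The group screen
reports raw p-values across the 30 × 5 feature-stage grid (no
multiplicity correction by default, Holm by flag) together with the
point-biserial correlation and its magnitude bin. PCA relevance operates
on the correlation structure (the features mix ms, ms², degrees and
ratios); components are retained as a fixed count (default 13) or by
cumulative variance, and a feature survives if any retained loading
reaches 0.2 in magnitude. Bland–Altman agreement pairs marks one-to-one
by nearest neighbor within 50 ms, reports mean difference and
mean ± 1.96 sd limits, and counts unmatched marks separately rather than
folding them into the differences.

# Problem sizes and numerical choices

The reference experiments in the tests and the acceptance script use: a
25-subject, 60-s, 1 kHz single-stage cohort for delineation and
agreement; three independently seeded full cohorts (25 subjects × 5
stages, 60 s) for the feature-based classifiers; three 25-subject basal
cohorts of 150 s at 100 Hz, cut into 300 windows of 50 samples, for the
CNN (subject-wise holdout of 5 subjects per seed); 200 null cohorts of
10 s at 250 Hz for type-I calibration; and 500 repetitions for the
repeated-CV protocol. Record duration defaults to 60 s (about 70 beats),
enough for stable interval statistics. These sizes are the package's
reference configuration; every generator parameter scales beyond them.

Other numerical conventions: all randomness flows from integer seeds
through a deterministic per-(subject, stage) stream hash, so cohorts are
bit-reproducible regardless of generation order and single records can be
regenerated in isolation; the caller's RNG state is always restored.
Ties in the subject majority vote go to the positive class. The
Pan–Tompkins thresholds initialize from the first two seconds of signal.

# Known limitations

* The delineator is polarity-sensitive by construction; `auto_invert`
  handles globally inverted leads but not beat-wise polarity changes.
* Arithmetic axis averaging breaks down near ±180°.
* The Q/S trough search operates on the raw signal and degrades under
  heavy noise, as the noise-robustness experiments show; only R detection
  is noise-hardened.
* The CNN is CPU-bound and meant for the study's modest scale, not for
  large corpora.
* Synthetic-cohort results quantify algorithmic correctness; no clinical
  claim follows from them.
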