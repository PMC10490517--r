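---
title: "Classifying driver mental engagement from fused EEG, SPR and ECG signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying driver mental engagement from fused EEG, SPR and ECG signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(engagefuse)
```

## The problem

A driver who is actively steering a vehicle is in a measurably different
physiological state than one supervising an autonomous system. Three
wearable modalities carry that contrast: scalp EEG (six channels at the
10/20 positions Fp1, Fp2, C3, C4, O1, O2, mastoid-referenced), endosomatic
electrodermal activity measured as the skin potential response (SPR, one
sensor per hand), and a two-lead chest ECG. All ten signals are acquired
synchronously at 200 Sa/s on one body sensor network, and the task is a
binary classification of 3 s windows: high mental engagement (manual
driving, label 0) versus low engagement (autonomous driving, label 1).

`engagefuse` implements the complete stack: recording I/O and repair, a
synthetic cohort generator, the signal-cleaning chain, two deep
convolutional fusion classifiers, and leave-one-subject-out (LOSO)
evaluation with accuracy, sensitivity, specificity, balanced accuracy (BA)
and geometric mean (GM).

## The study protocol the generator emulates

Each of 19 subjects completes three manual highway drives of roughly
7 min at ~120 km/h on a 14 km course with six road-works obstacles
(200 m long, 2 km apart, the first at 2 km), followed by a ~20 min
autonomous session (the same 14 km plus 27 obstacle-free km). Because the
recorded dataset is available only on request, the package ships a
first-class generator, [generate_cohort()], whose defaults encode exactly
these conditions.

The class-conditional signal model follows the physiological premise that
manual driving raises engagement:

* **EEG** — each channel is a sum of band-limited Gaussian processes
  (delta 1–4, theta 4–8, alpha 8–13, beta 13–30 Hz) over a 1/f
  background. Under high engagement frontal theta power rises by the
  factor `1 + eeg_effect` and occipital alpha power falls by the same
  factor (beta rises mildly). The default `eeg_effect = 0.5` is a
  moderate, physiologically plausible shift; 0 removes the contrast
  entirely.
* **ECG** — a Gaussian-bump PQRST train with 3% RR jitter at 85 bpm
  (manual) versus 70 bpm (autonomous); two leads differ in gain and
  noise.
* **SPR** — a shared slow tonic level plus phasic responses (0.3 s rise,
  2.5 s decay) at 6/min versus 1.5/min; the two hands share the
  physiology and differ in noise and motion artifacts.

Artifacts are injected at configurable rates with ground-truth
bookkeeping: blinks on Fp1/Fp2, low-frequency drift on C3/C4, electrode
pops on O1/O2, motion spikes on one SPR hand at a time, respiration-band
baseline wander on the ECG, and dropped-packet runs of exact zeros per
sensor group (the acquisition GUI writes literal zeros when a packet is
missed).

What the generator deliberately does **not** model: volume-conducted EEG
source geometry, EMG/EOG crosstalk, heart-rate variability structure
beyond RR jitter, inter-subject anatomical variability, or vehicle
dynamics beyond a 1-D longitudinal position trace. Tests passing on
synthetic cohorts therefore demonstrate that the pipeline and classifiers
recover class structure of the kinds injected, at the configured effect
sizes — not that accuracies measured on real recordings are reproduced.

## The cleaning chain

`preprocess_session()` applies, in fixed order:

1. **Zero-gap repair** — maximal runs of exact zeros are linearly
   interpolated between their nonzero neighbors (edges: constant
   extrapolation). A sample is treated as an inserted zero iff it is
   exactly 0.0; biological signals are almost surely nonzero at float
   resolution.
2. **Trace alignment** — the simulator CSV defines the session length;
   the recording is truncated to it (deficits over 1 s are errors).
3. **Notch** — 4th-order Butterworth band-stop, 46–54 Hz, zero phase.
   All IIR filtering is forward–backward with steady-state initial
   conditions and autoregressive (Burg) forecast padding, which continues
   oscillations phase-coherently so no start-up transient reaches the
   data.
4. **EEG band-limiting** — linear-phase windowed-sinc (Hamming) FIR
   filters, 4 Hz high-pass (2 Hz transition) then 45 Hz low-pass (5 Hz
   transition), with the group delay compensated so EEG stays aligned
   with SPR/ECG.
5. **Amplitude rejection** — any 1 s block in which a band-limited EEG
   channel exceeds 500 µV is excluded from ASR calibration and excised
   with the obstacle windows. This replaces the manual visual inspection
   of the original protocol with a reproducible criterion.
6. **ASR** — artifact subspace reconstruction: the cleanest blocks (by
   robust channel-RMS z-score) form the calibration data; per-component
   rejection thresholds are `mu + cutoff_k * sigma` of component RMS over
   1 s calibration blocks (`cutoff_k = 20`, a deliberately conservative
   default that touches only gross artifacts); each 0.5 s sliding window
   is eigendecomposed and offending components are reconstructed from the
   calibration subspace; windows blend by raised-cosine overlap-add.
7. **SPR fusion** — at each instant the channel whose first difference
   has lower local energy over a 1 s window wins; selections cross-fade
   over 100 ms.
8. **ECG** — the lead with the higher SNR (QRS-band 5–25 Hz power over
   out-of-band power plus a robust high-frequency noise term) is kept and
   high-passed at 0.5 Hz (2nd-order Butterworth, zero phase).
9. **Obstacle excision** — samples whose longitudinal position lies in
   `[p - 500, p + 200 + 500)` m around any obstacle start `p` are removed
   from every channel simultaneously (half-open intervals, 0-based
   sample convention internally documented as R 1-based).
10. **Segmentation** — non-overlapping `round(3 s × 200 Sa/s) = 600`
    sample windows, cut within one session only (never across excision
    joints), trailing remainder dropped; manual sessions labeled 0, the
    autonomous session 1.

## The two fusion networks

Both classifiers are four-block deep ConvNets operating on raw segments.

**Data-level fusion** consumes one 600 × NChannels array (NChannels 6–8
as sensors are added). Block 1 applies a temporal convolution (25 kernels
of length 5) followed by a spatial convolution spanning all input rows,
then batch normalization (trainable scale and shift), ELU, max-pool
(size 2, stride 2, floor) and dropout 0.38. Blocks 2–4 are 50/100/200
filter convolutions of length 5 with the same trailing stages. The time
axis follows 600 → 596 → 298 → 294 → 147 → 143 → 71 → 67 → 33, so the
flatten yields 6,600 features, closed by a 2-unit softmax dense layer
with an L2 penalty of 1.3 on its weights.

**Feature-level fusion** runs one such branch per sensor group — the EEG
branch with both first-block convolutions, the single-channel SPR and ECG
branches with the temporal convolution only — at dropout 0.5,
concatenates the flattened branch outputs (6,600 each) and closes with a
500-unit ReLU dense layer and a 2-unit softmax layer, both L2-penalized
at 0.7.

Training minimizes categorical cross-entropy with Adam (batch 128,
default learning rate 1e-3) for at most 200 epochs (patience 50) at the
data level and 50 epochs (patience 20) at the feature level. The
trainable-parameter counts of the six sensor configurations (149,477 /
150,102 / 150,727 for data-level EEG, EEG+one channel, all; 3,437,777 /
6,870,277 / 10,302,777 for the feature-level counterparts) are verified
in the test suite against an independent closed-form layer-arithmetic
oracle.

### Design choices the protocol leaves open

* **Early-stopping monitor** — patience without a monitored quantity is
  undefined; we carve a seeded stratified 10% split from the training
  segments and monitor its loss, restoring the best weights.
* **Input standardization** — raw µV and mV scales differ by orders of
  magnitude, and the data-level model concatenates them into one array;
  every channel is z-scored with training-set statistics (computed once
  over the training segments, reused at prediction). Per-segment scoring
  was rejected because it erases class-informative amplitude structure.
* **Batch-norm inference statistics** — running means/variances use a
  cumulative average over the first updates and an exponential one
  (momentum 0.9) thereafter, so inference-mode statistics are usable even
  after very short training runs.
* **Ties** — argmax ties resolve to the lower class index; max-pool ties
  take the earlier sample.
* **Positive class** — the protocol never states which class is positive
  for sensitivity/specificity; we define positive = label 0 (high
  engagement), configurable, and record it in every report.
* **Balancing** — training folds are balanced by seeded undersampling of
  the majority class (oversampling would leak duplicated segments into
  the early-stopping split); test folds are never balanced.
* **Undefined metrics** — a fold with an empty denominator reports `NA`
  and is excluded from that metric's cohort aggregate with a warning,
  rather than being coerced to 0.

### Numerical implementation

The networks are implemented in the package itself: convolutions are
im2col gathers feeding BLAS matrix products, with the layer kernels
(im2col, batch-norm, ELU, pooling, dropout, Adam) in C++ via Rcpp. The
first-block temporal and spatial convolutions compose linearly, so they
are evaluated as a single gemm with the effective kernel
`W_spatial ∘ W_temporal` while their parameter tensors remain separate
for counting and optimization; gradients are mapped back by the chain
rule. Backpropagation is verified against central finite differences in
the test suite (agreement ~1e-9 relative). Dropout uses R's RNG, so a
single `set.seed()` determines training end to end.

## Evaluation

`loso_evaluate()` trains on the balanced union of all other subjects'
segments and tests on the held-out subject's full, imbalanced segment
set, producing per-subject confusion counts and the five metrics in
percent:

* accuracy = (TP + TN) / total
* sensitivity = TP / (TP + FN), specificity = TN / (FP + TN)
* BA = (sensitivity + specificity) / 2
* GM = sqrt(sensitivity × specificity)

BA and GM are prevalence-independent, which matters because the test sets
are imbalanced (three manual sessions versus one longer autonomous one).
`window_length_sweep()` re-cuts cleaned sessions at other window lengths
and repeats the evaluation; the architecture accepts any window of at
least 76 samples (the receptive-field minimum of the conv/pool chain).

## Problem sizes used by the test suite

The automated tests run the full pipeline end to end at reduced scale,
chosen once as a desk-sized version of the protocol:

* **Separability cohort** — 5 subjects, three 150 s manual sessions and
  one 80 s autonomous session each (~174 segments/subject), no obstacles,
  with large engagement contrasts (`eeg_effect = 1.5`, 95 vs 65 bpm,
  10 vs 0.5 SPR events/min). Training uses learning rate 3e-3 with at
  most 10 (data-level) or 8 (feature-level) epochs — a handful of Adam
  steps suffices at these effect sizes, and the larger step compensates
  for the few updates a small balanced training set affords.
* **Null cohort** — 5 subjects with identical class-conditional
  distributions; session durations are chosen so each subject's test set
  is roughly class-balanced, making chance level interpretable as ~50%.
  LOSO accuracy on this cohort is required to stay in [40%, 60%].
* **Micro cohort** — 3 subjects with very short sessions, used for
  protocol-shape and determinism checks.

On the separability cohort both architectures reach LOSO mean accuracy
well above 70% and the feature-level network is at least as accurate as
the data-level one on average over three seeds, consistent with the
general advantage of feature-level fusion for heterogeneous sensors.
Accuracies measured on the real cohort are not reproduction targets
here: those recordings are not public.

## Known limitations

* The ASR implementation follows the standard calibration /
  eigendecomposition / reconstruction procedure but is not a port of any
  particular toolbox; parameter defaults (60 s calibration, cutoff 20,
  0.5 s windows) are package choices, as the protocol names the algorithm
  without parameters.
* The ECG lead-selection SNR estimator is a package definition; the
  protocol states only that the higher-SNR lead was kept.
* Training on a single CPU in R, even with the C++ kernels, is orders of
  magnitude slower than a GPU deep-learning stack; full-protocol budgets
  (200 epochs, 19 subjects) are practical overnight rather than in
  minutes. All defaults nevertheless encode the full protocol, and scale
  is reduced only through explicit configuration.
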