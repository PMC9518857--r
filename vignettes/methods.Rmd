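---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`speechscreen` classifies participants as mTBI-positive or control from a
single read-speech recording. This vignette is the package's account of the
science inside it: the feature model, the network, the optimisation and
evaluation machinery, what the synthetic data generator does and does not
emulate, and the design decisions taken where the underlying method left
genuine freedom. It states no empirical result that the test suite does not
itself compute.

## 1. MFCC feature model

Voiced speech is shaped by the vocal-tract filter; its slowly varying
spectral envelope carries most of the linguistically and clinically relevant
information. Mel-frequency cepstral coefficients compress that envelope into
a handful of numbers per ~46 ms analysis frame:

1. **Pre-emphasis** `y[t] = x[t] − α·x[t−1]` with α = 0.97 flattens the
   natural −6 dB/octave tilt of glottal excitation. The stage is standard;
   0.97 is the conventional coefficient.
2. **Framing**: 2048-sample windows advancing by 512 samples (hop). At the
   nominal 44.1 kHz recording rate that is 46.4 ms frames every 11.6 ms.
   Signals shorter than a frame, and ragged tails, are zero-padded so
   `n_frames = 1 + ceiling((L − 2048)/512)`; a signal delayed by exactly one
   hop therefore reproduces the same interior frames one row later (tested).
3. **Windowing**: the *periodic* Hann window (`0.5 − 0.5·cos(2πk/N)`,
   `k = 0..N−1`), whose sum is exactly N/2 — the DFT-analysis form, as
   opposed to the symmetric filter-design form.
4. **Spectrum**: squared-magnitude FFT, keeping the 1025 non-negative
   frequency bins.
5. **Mel filter bank**: 128 triangular filters with centres equally spaced
   on the mel axis between 0 Hz and Nyquist. The mel scale is
   `Mel(f) = C·log10(1 + f/f₀)` with corner frequency f₀ = 700 Hz and
   `C = 1000/log10(1 + 1000/700)` — the constant is *defined* so that
   1000 Hz maps to exactly 1000 mels, and is kept unrounded internally
   (2595.009…; the familiar rounded 2595 is asserted in the tests).
   Triangles are constructed on the continuous Hz axis and *evaluated at*
   the FFT-bin centre frequencies. We deliberately do not snap triangle
   edges to integer bins: at 128 filters on a 2048-point FFT the
   low-frequency mel spacing (~19 Hz) is smaller than a bin (21.5 Hz), so
   integer snapping collapses adjacent low filters onto the same bin and
   produces empty filters; evaluating the continuous triangles on the bin
   grid preserves positivity, unimodality and full band coverage (all
   tested). No area normalisation is applied.
6. **Log compression**: common (base-10) logarithm, with energies floored
   at `1e-10 × max(energy)` of the clip so silence yields a constant floor
   cepstrum rather than −∞.
7. **DCT**: orthonormal type-II transform of the 128 log energies; the
   first 13 coefficients are kept, lowest ("most significant") first.

Every one of these choices is recorded in the `mfcc_dialect` object that
travels with extracted features, and the whole pipeline is verified against
an independent numpy/scipy implementation configured to the identical
dialect (20 seeded clips, 1e-5 absolute tolerance per coefficient; observed
agreement is ~1e-14).

**Normalisation.** Whether features were normalised before training is not
specified by the method we follow. We z-score each coefficient using
*training-partition statistics only*, applied identically to validation and
test data at predict time (the statistics ride on the model object, so no
leakage). Raw cepstra put coefficient 0 at magnitudes of tens while higher
coefficients sit near zero; plain SGD at small learning rates cannot train
across that scale spread. Standardisation can be disabled with
`training_config(standardize = FALSE)`.

**Segmentation.** Clips are cut into consecutive, non-overlapping blocks of
`frames_per_segment` rows (default 100 ≈ 1.16 s); the trailing remainder is
dropped. Segment length and overlap were not specified upstream; we chose
non-overlapping blocks to keep segments statistically independent within a
participant, and a length around one second as the shortest window that
spans several syllables and a typical pause. Each segment inherits its
participant's label, and *evaluation is segment-level by default*: the
published sensitivity/specificity admit integer reconstructions only at
segment counts (18/19 ≈ 94.7%, 25/29 ≈ 86.2%), not at the ~9 test
participants a 20% split of 46 allows. Participant-level evaluation
(mean-score aggregation, i.e. majority vote at the 0.5 threshold) is
available via `evaluate_model(granularity = "participant")`.

## 2. The Bi-LSTM-A network

Architecture, in order: bidirectional LSTM (sequence output) → LSTM
(sequence output) → additive temporal attention (one context vector) →
dense + ReLU → dropout → dense + ReLU → softmax over 2 classes.

Three points were genuinely under-determined and are package decisions:

* **"Bidirectional LSTM, 512 units"** is read as the *total* concatenated
  output width — 256 units per direction. The per-direction reading gives
  >3 M parameters, inconsistent with the reported "around 1 million
  parameter" lightweight model; the total reading lands at 1,513,794
  (asserted against closed forms in the tests). Both readings are available
  via `model_spec(bidirectional_reading=)`.
* **Attention form**: additive (Bahdanau-style) scoring
  `e_t = vᵀ tanh(W h_t + b)` with a 512-unit scorer, softmax over
  timesteps, context = weighted sum of the second LSTM's sequence output.
  The attention mechanism was cited generically upstream with no equations;
  additive attention is the standard choice for RNN sequence
  classification. The "512 units" are read as the hidden scorer width.
* **Dense activations**: ReLU (unstated upstream).

The network is implemented in RcppArmadillo (no R deep-learning framework
is assumed anywhere): batched forward pass and full backpropagation through
time, cross-entropy loss, inverted dropout (masks drawn in R so the whole
computation is deterministic given the R seed). Gradients are verified
against central finite differences for every parameter tensor, with and
without dropout. LSTM forget-gate biases initialise to 1, other biases to
0, weights Glorot-uniform.

`unit_scale` shrinks all widths proportionally (e.g. 1/8 for desk-scale
tests) while preserving the architecture; `count_parameters()` gives the
exact closed-form parameter count for any spec.

## 3. Training

SGD with momentum (default: learning rate 1e-4, batch 128, momentum 0.9, at
most 89 epochs — the published tuned values), shuffled mini-batches over
training-partition segments, early stopping on validation loss with
patience 10 and restoration of the best-epoch weights. "Epochs 89" is
interpreted as the *budget* (`max_epochs`); the early stopper decides the
realised epoch. Two safeguards beyond the stated method: a global
gradient-norm clip (default 5; disable with `clip_grad_norm = Inf`) and an
immediate abort with diagnostics on non-finite loss. When the training set
is smaller than the batch size, each epoch is one batch.

Splits are participant-level (60/20/20), stratified by class under a
largest-remainder quota constrained to the overall nearest-integer sizes
(46 participants → 28/9/9), with each partition holding at least one
participant of each class whenever the quota can be rebalanced to allow it.
Classes with fewer than 3 participants trigger a documented fallback to an
unstratified split with a warning. A programmatic leakage guard inside
`train_model` asserts that no test participant's segments reach training or
early stopping.

The PSO fitness of a hyperparameter assignment is the best validation loss
of a reduced-budget training run (loss, not accuracy, because the training
diagnostics upstream are reported as loss curves); training failures return
`+Inf` so the swarm survives bad regions.

## 4. Particle swarm optimisation

Hyperparameters live in ordered discrete candidate sets; particles fly in
the continuous per-dimension index space `[0, k−1]` and decode by
clamp-then-round, with exact half-integer ties rounding *down* (2.5 → index
2) — an arbitrary but documented and tested convention. The update is the
canonical `v ← w·v + c₁r₁(pbest−x) + c₂r₂(gbest−x)` with
constriction-equivalent coefficients w = 0.729, c₁ = c₂ = 1.49445 (none
were specified upstream), velocities clamped to the dimension range and
absorbing walls at the position bounds (a velocity component that drives a
particle into a clamped bound is zeroed).

Two decisions depart from our own first draft, because implementation
proved it wrong on the package's own acceptance property (PSO must match
exhaustive search on ≥9/10 small tabulated spaces with 15 particles × 30
iterations):

* **Anti-stagnation re-scatter** (`rescatter_duplicates`, on in
  `pso_optimize`, off in the raw `step_swarm`): in a discrete space many
  continuous positions alias to one cell, so a converged swarm spends its
  entire remaining budget re-evaluating the incumbent. After each update,
  particles decoding to the current global-best cell are re-scattered
  uniformly with probability 1/2. With it, the exhaustive-match property
  holds at 9–10/10 across seed families; without it, 4–8/10.
* **Early-stop patience defaults to the full budget** in `pso_optimize`: a
  patience of 10 iterations stops a 30-iteration run around iteration 11
  and measurably costs solution quality on cheap fitness tables. For
  expensive fitness (model training) the experiment config keeps a
  patience of 10 by default — there the trade is worth it.

The stopping rule itself (budget exhausted, or `patience` iterations
without global-best improvement) was an open question upstream and is our
choice.

## 5. Synthetic cohort generator

The generator exists so that every downstream stage is exercisable with no
clinical audio. It emulates exactly the biomarkers the screening rationale
names, via classical source-filter synthesis:

* **Source**: a glottal pulse train at the speaker's f₀ with relative
  period jitter (`jitter_sd`).
* **Filter**: a cascade of three second-order resonators at vowel formant
  targets (/a/, /i/, /u/ per syllable), scaled by the profile's
  `formant_shift` and a per-speaker vocal-tract factor.
* **Prosody**: syllables of mean length `1/syllable_rate` (log-normal
  variation) under a raised-cosine amplitude envelope with a 0.15 floor —
  adjacent syllables coarticulate, so voicing never drops to silence unless
  a pause is explicitly inserted (this makes "no pauses" testable as "no
  silent gap longer than a pitch period"). Pauses are scheduled
  quasi-periodically: the gap between pauses, in syllables, is drawn around
  the mean implied by the profile's pauses-per-minute, and pause lengths
  are gamma(shape 4) around `pause_length_mean` — speakers pause at
  phrase-like boundaries, not memorylessly.

The control profile is 4.5 syllables/s, 6 pauses/min of 0.35 s, unit
formant shift, 1% jitter; the full-effect positive profile is 3.2
syllables/s, 14 pauses/min of 0.8 s, formant shift 0.94, 5% jitter —
directions follow the impaired-speech literature (slowed, pause-heavy,
spectrally shifted, rougher voice); magnitudes are fixture choices, not
clinical claims. `effect_size` interpolates the positive profile linearly
from the control profile, so `effect_size = 0` is an exact null world.
Speakers within a class differ by a vocal-tract factor (sd 3%) and f₀
(120 ± 12 Hz) — enough speaker variability that a classifier must
generalise across voices, little enough that the class signal is the
dominant structure, which is precisely the regime the end-to-end acceptance
test requires (held-out AUROC ≥ 0.9 at full effect, ~0.5 at null).

What the generator does *not* emulate: phonetics beyond three vowels,
consonants, prosodic f₀ contours, accents, channel/recording noise beyond a
−54 dB floor, or any pathology of real mTBI speech. A green end-to-end test
therefore establishes that the pipeline can learn and carry a planted
acoustic class difference through to held-out evaluation — not that the
model detects concussion.

## 6. Evaluation

Scores are softmax probabilities of the positive class per segment. The
confusion matrix thresholds at 0.5 (no threshold was specified upstream).
ROC curves sweep the unique scores from high to low; tied scores move
diagonally in one simultaneous step, which makes the trapezoidal area
*identically* equal to the Mann-Whitney pairwise estimator with half-credit
ties — asserted to 1e-9 on random tied and untied score sets. The exact
identity `accuracy = prevalence·sensitivity + (1−prevalence)·specificity`
is also property-tested.

## 7. Numerical and degenerate-input conventions

* Silence (all-zero clips): log-energy floor gives a constant cepstrum;
  write/read round trips preserve it exactly.
* WAV I/O scales by 32767 symmetrically in both directions; round-trip
  error is below half a 16-bit quantisation step.
* `truncate_clip` rounds the window to
  `round((end−start)·rate)` samples, guaranteeing length composability on
  sample-aligned bounds.
* Matrices shorter than one segment yield an empty segment list with a
  warning, not an error.
* ReLU subgradient at exactly 0 is taken as 0; with zero-initialised
  biases and a fully-masked dropout row this is observable in finite
  differences (the gradient tests perturb biases off the kink).
* The scaled-down acceptance experiment uses 50-frame segments (0.58 s)
  rather than the 100-frame default: 3-second clips yield 259 frames, so
  100-frame segments would discard 23% of the audio and halve the training
  set.
* The null-cohort acceptance band is evaluated as the mean held-out AUROC
  across the three seeds: a single 40-segment test set gives a null AUROC
  standard deviation near 0.19, so a per-seed band of [0.35, 0.65] would
  fail by pure chance roughly 40% of the time at exact null.

## 8. Known limitations

* The network trains on CPU via BLAS; full-scale training (1.5 M
  parameters, 128-batch) is minutes-per-epoch territory, not suitable for
  large cohorts.
* The PSO searches discrete candidate sets only; continuous-parameter PSO,
  inertia schedules and topologies are out of scope.
* Participant-level aggregation uses mean scores; calibrated probability
  aggregation is not attempted.
* The JSON feature file stores full-precision doubles and grows ~25 bytes
  per coefficient; for very large cohorts a binary store would be
  preferable.
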