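---
title: "Per-second apnea detection from SpO2 with a transformer encoder: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-second apnea detection from SpO2 with a transformer encoder: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Obstructive sleep apnea (OSA) is scored from attended polysomnography in
30-second epochs, a slow and expensive process. Pulse oximetry alone is an
attractive screening channel: obstructive events leave a characteristic
signature in SpO2 — a desaturation of 3--4% from the preceding baseline,
lasting tens of seconds. `spo2former` detects these events directly from
the raw 1 Hz SpO2 series and emits one apnea/normal decision **per
second**, so a physician can inspect exactly which seconds drove a call.
Per-patient screening follows by reconstructing discrete events from the
per-second decisions and applying the standard AHI ≥ 5 events/hour rule.

## The model

A window of `n` seconds of min-max-normalized SpO2 enters as a length-`n`
sequence of scalars. The model is an encoder-only transformer:

1. **Input embedding.** A pointwise linear lift of each scalar to a
   `d_model`-dimensional vector (default `d_model = 32`). This is the
   smallest mechanism realizing `Z_i = inputE(x_i) + PE(i)`.
2. **Positional stage.** One of four interchangeable variants (below).
3. **Encoder stack.** Four identical layers. Each layer applies multi-head
   scaled dot-product self-attention,
   `Attention(Q, K, V) = softmax(Q K' / sqrt(d_k)) V`,
   with `n_heads = 4` heads of depth `d_k = d_model / n_heads`, then a
   position-wise feedforward block (`d_model -> d_ff -> d_model`, ReLU,
   `d_ff = 64`). Both sublayers use residual connections, dropout
   (default 0.1) and layer normalization in the *post-norm* arrangement of
   the original transformer; a pre-norm option was considered and rejected
   to keep the layer faithful to the classical layout the architecture
   defers to.
4. **Head.** A pointwise linear map `d_model -> 1` with a sigmoid, one
   apnea probability per second. A mean-pool segment-level head is
   available behind `model_config(head = "segment")` for comparison, but
   per-second labeling is the package's point.

`d_model = 32` follows the sinusoidal-table depth; `n_heads = 4` and
`d_ff = 64` are deliberately small, configurable defaults.

### Positional-encoding variants

* `none` — the encoder is order-blind (a "bag of seconds"); kept as the
  ablation baseline.
* `constant` — the normalized sample index
  `PE(i) = (i - 0) / (n - 1)`, broadcast across the embedding depth and
  added to the input embedding. For `n = 1` the encoding is defined as 0
  (the min = max convention of the normalization) so the operation is
  total.
* `sinusoidal` — the classical
  `PE(pos, 2i) = sin(pos / 10000^(2i/d_model))`,
  `PE(pos, 2i+1) = cos(...)` table, canonical size 64 x 32. A fixed
  length-64 table cannot cover windows up to 360 s, so the table is built
  at `max(sequence_length, 64)` rows and truncated to the window; the
  closed form extends naturally and preserves the relative-position inner
  product property.
* `learnable` — a 1-D convolutional autoencoder (CAE): strided
  convolutions (kernel 7, stride 2, ReLU, dropout in between) downsample
  the window to a latent sequence, transposed convolutions (ReLU)
  upsample it back, and a final kernel-7 stride-1 convolution emits a
  reconstruction of exactly the input length. The reconstruction
  **replaces** the raw input fed to the transformer; an additive variant
  (`pe_additive = TRUE`) adds it to the input instead, exposing the
  alternative reading of the additive-combination formula.

CAE choices that are genuinely open, fixed here once:

* **Depth and filters.** Two downsampling layers with filters `c(32, 16)`
  — the smallest stack that is still a multi-layer encoder — then transposed convs
  with channels 16 and 32 and the final 1-channel conv. All configurable
  via `cae_config()`.
* **Padding.** Same-padding everywhere, so each stride-2 layer maps length
  `L` to `ceiling(L / 2)` exactly, and the transposed convolutions are
  implemented as the exact adjoint of the corresponding strided
  convolution with an explicit output-length target. This guarantees
  output length equals input length for *every* window length (10--360 s),
  not just multiples of 4.
* **Dropout placement.** Between encoder layers only; whether the decoder
  should also be regularized is an open choice, and the smaller one was
  taken.
* **Training signal.** The CAE trains jointly with the classifier through
  the classification loss alone — one model, one loss. No separate
  reconstruction pretraining is performed (an auxiliary reconstruction
  term was considered and left out to keep the default faithful to a
  single end-to-end model).

## Preprocessing pipeline

* **Missing samples** are dropped together with their labels
  (`drop_missing()`), not interpolated; dropping shifts absolute time, so
  event annotations are invalidated and removed alongside.
* **Normalization** is min-max to `[0, 1]`, applied *independently per
  segment* (`window_record()` default); a per-record mode exists behind a
  flag. A constant window maps to all zeros rather than erroring.
* **Windowing** uses non-overlapping windows by default (stride = length):
  overlap at test time would duplicate seconds, and overlap at train time
  is an augmentation option, not the baseline. Trailing remainders shorter
  than one window are discarded, never padded.
* **Splits.** `split_holdout()` offers segment-random (the default) and
  patient-grouped modes; the grouped mode exists because segment-random
  splitting of overnight records risks leakage between adjacent windows of
  one patient, which matters whenever per-patient generalization is the
  claim. `kfold_partition()` provides seeded 5-fold CV.

## The synthetic cohort

`simulate_record()` generates 1 Hz overnight SpO2 with per-second labels:

* baseline at `baseline_mean` (default 97%) plus a truncated AR(1) drift
  (`rho = 0.995`, stationary sd `baseline_sd = 0.5%`, clipped at 3 sd) —
  the drift defeats trivial global thresholding;
* events at a Poisson rate matching `target_ahi`, placed uniformly with
  rejection and a 10 s refractory gap, durations uniform on 10--60 s;
* desaturations of depth uniform on 3--4% (the standard scoring
  criterion), piecewise-linear: descent over the first third of the event,
  recovery over the remainder (exponential recovery optional);
* i.i.d. Gaussian noise (`noise_sd = 0.3%`), then optional missing samples
  and low artifact spikes (outside the clean envelope), applied *after*
  labeling;
* labels are 1 exactly on annotated event seconds, so label runs and the
  event table are interconvertible.

What the simulator does **not** emulate: hypopnea-vs-apnea subtypes,
arousal-linked events without desaturation, heart-rate co-variation,
realistic artifact statistics of a stroke-unit monitor, and sleep/wake
structure. Tests passing on this cohort therefore demonstrate that the
pipeline can learn and score desaturation morphology under noise and class
imbalance — not clinical performance on hospital data.

## Training protocol

`train_config()` defaults are Adam, batch 32, initial learning rate 1e-5,
reduce-on-plateau with factor 0.2 (patience 5 epochs, minimum improvement
1e-4, the conventional value), up to 40 epochs, unweighted loss. The loss is per-timestep
binary cross-entropy; `class_weighting = "balanced"` switches to
inverse-frequency weights.

The package's own desk-scale experiments (tests and the acceptance
script) deliberately deviate in two documented ways:

* **learning rate 1e-2**: 1e-5 is calibrated to roughly a million training
  samples on GPU over 40+ epochs; on a 540-window synthetic cohort trained
  for at most 10 epochs (~170 Adam steps) it cannot move the parameters
  appreciably, and a proportionally larger step is the matched choice;
* **balanced class weighting**: with ~17% positive seconds an unweighted
  model is well-ranked (AUC) but poorly calibrated at the 0.5 threshold,
  which would make the AHI-from-events stage vacuous at this scale.

Problem sizes used by the test suite: a 20-patient x 1 h cohort (two
held-out extreme patients, target AHI 0 and 40), sequence length 120 s,
at most 10 epochs, three seeds; the positional ablation runs a 2-layer
`d_model = 16` model on 60 s windows of a purely position-labeled task.
These sizes were chosen so the full suite runs on a single CPU in minutes
while still exercising every stage at the package's default model
dimensions.

## Evaluation

Per-second metrics come from the confusion matrix at threshold 0.5:
accuracy, recall (sensitivity), precision, specificity, and F1 (harmonic
mean of precision and recall). Zero-denominator conventions: recall,
precision and specificity are 0 when their denominator is 0; F1 is 0 when
precision + recall is 0. ROC AUC is threshold-free and computed via pROC
(trapezoidal; equal to the Mann-Whitney pairwise probability with ties
counted one half — the test suite checks this against a brute-force
comparator).

Per-patient screening (`per_patient_report()`): per-second scores are
thresholded, maximal runs of at least 10 s (the standard minimum duration
of a scored respiratory event) become events — optionally after bridging
short gaps — and AHI = events / recorded hours; OSA is called at
AHI ≥ 5. The default protocol scores every patient with one model trained
on the held-out split; leave-one-patient-out retraining is possible with
the provided split tools but is expensive and not the default. Trailing
seconds not covered by any full window are excluded from metrics, not
imputed.

## Numerical choices

* Layer-norm epsilon 1e-5; softmax rows are shifted by their maximum
  before exponentiation; probabilities are clamped to
  `[1e-12, 1 - 1e-12]` inside the loss.
* Glorot-uniform initialization everywhere; for convolutions the fans are
  `kernel x channels`.
* All stochastic stages (initialization, shuffling, dropout, simulation,
  splits) run under explicit seeds through one RNG helper that restores
  the caller's RNG state, so runs are bit-reproducible in R's default
  single-threaded arithmetic.
* Backpropagation is hand-derived; the test suite validates every
  parameter group against central finite differences on a small model,
  and confirms that gradients reach the CAE weights through the
  classification loss alone.

## Known limitations

* Pure-R training is CPU-bound: roughly 10--15 s per epoch on the
  540-window synthetic cohort. The implementation favors clarity and
  verifiability over throughput; it is not a tool for training on
  millions of samples.
* The sinusoidal table extension beyond 64 rows and the CAE
  depth/filter/dropout choices are reasoned defaults; alternatives remain
  one configuration flag away.
* AHI estimation counts reconstructed events over *recorded* time;
  without sleep staging, total recording time stands in for total sleep
  time, which biases AHI downward on real recordings with long wake
  periods.
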