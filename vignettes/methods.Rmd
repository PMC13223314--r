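---
title: "Movement classification from two-channel sEMG: models, protocols, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement classification from two-channel sEMG: models, protocols, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Myoelectric prosthesis control decodes the user's intended movement from
surface electromyography (sEMG). Low-density setups — here two bipolar
channels over the forearm flexor and extensor compartments — are cheap and
clinically practical but put all the burden on signal processing: the
classifier must tell several finger movements apart from 250 ms of raw
two-channel voltage, must survive the large signal differences between
people, and must be adaptable to a new user from a minimal calibration
recording.

`csaemg` implements an end-to-end pipeline for this problem:

1. sliding-window segmentation of continuous recordings,
2. leakage-free per-channel standardization,
3. unsupervised feature learning with a convolutional sparse autoencoder
   (CSAE),
4. a lightweight attention-pooled classifier head on the frozen encoder,
5. few-shot calibration to unseen users,
6. incremental expansion of the class set by softmax weight transfer, and
7. leave-one-subject-out (LOSO) evaluation with mean ± standard-error
   reporting, plus classical and neural benchmark pipelines.

Because the package must be testable offline, it also contains a seeded
synthetic sEMG generator whose cohorts drive all tests and examples.

# Segmentation and standardization

A trial is cut into windows of `window_ms` (default 250 ms) advanced by
`stride_ms` (default 125 ms, i.e. 50% overlap). A decision every 125 ms on
250 ms of context is the standard compromise between controller latency and
information per decision. Window `i` (0-based) starts at sample
`i * stride_samples`; an incomplete tail is dropped so every segment has
exactly `round(window_ms * fs / 1000)` samples — the models need a fixed
input shape. With `L` samples, window `T` and stride `S` (in samples) the
segment count is `floor((L - T) / S) + 1`.

The standardization scaler (per-channel mean and standard deviation, pooled
over all training segments) is fitted **only** on the source-domain training
partition of a fold and then reused for validation, test, target-subject and
expanded-class data. Fitting anywhere else would leak evaluation data into
the preprocessing. Channels are standardized separately because the two
sensors sit on different muscles. A zero-variance channel is floored at
`1e-8` so degenerate synthetic inputs cannot divide by zero.

# Leave-one-subject-out partitioning

Each fold holds one subject out entirely (the *target*); the remaining
subjects form the *source domain*. Within the source domain trials are
assigned chronologically: trials 1–4 train, trial 5 validates, trial 6 is
the held-out test. The target subject contributes trial 1 as the few-shot
calibration set, trial 2 for validation during calibration, and trials 3–6
as the final unseen-user test. `assert_split_plan()` enforces the leakage
guards (target not in source; disjoint trial lists per domain) on every
plan, and `run_loso()` aborts if they fail.

# The convolutional sparse autoencoder

The encoder compresses a standardized segment `X (T x C)` into a latent map
`Z (T' x D)` through two strided 1-D convolution blocks (LeakyReLU
activations) and a stride-1 bottleneck convolution; the decoder mirrors it
with transposed convolutions of identical strides and a final linear
convolution back to `T x C`. Strided convolutions replace pooling so the
downsampling itself is learned; the mirrored strides make the
encoder/decoder composition restore the input shape exactly (this is a
property-tested invariant). Padding is "same"-style: a layer with kernel
`k >= stride s` pads `k - s` samples, so `T` must divide by the stride
product — checked at build time.

Training minimizes

```
L = mean((X - Xhat)^2) + lambda * sum(|Z|) / N
```

the mean squared reconstruction error over every element of the batch plus
an L1 activity penalty on the emitted (post-activation) bottleneck map. The
penalty sums `|Z|` over all activations and divides by the batch size `N`,
so `lambda`'s meaning does not depend on the batch size; the decomposition
`loss(lambda) = loss(0) + penalty(lambda)` holds exactly and is asserted in
the tests. A small `lambda` biases the code toward fewer, stronger
activations; a large one visibly degrades both reconstruction and the
downstream classifier (the mechanism behind the sweep in
`lambda_sweep()`). The default is `lambda = 1e-7`.

Optimization is AdamW (decoupled weight decay `1e-4`) with He-Normal
initialization, minibatch shuffling, a reduce-on-plateau learning-rate
schedule, early stopping on the validation loss, and restoration of the
best-validation parameters. The identical loop trains every model in the
package, so freeze semantics and callbacks cannot drift between stages. All
randomness flows through named substreams of one seed: the same
configuration and seed reproduce every parameter bit-for-bit.

The whole engine (convolutions via im2col/col2im with compiled gather and
scatter kernels, transposed convolutions as exact adjoints, attention,
LSTM, AdamW) is implemented in the package; every layer's backward pass is
validated against central finite differences at relative tolerance `1e-4`
in the test suite.

Reconstruction quality is summarized by `r2_reconstruction()`: the pooled
coefficient of determination `1 - SSE/SST` with `SST` about the batch mean,
so 1 is a perfect reconstruction and 0 is the score of predicting the mean
everywhere.

## Architecture defaults

The full-scale defaults (`csae_config()`) target 1000-sample segments
(250 ms at 4 kHz): conv I 32 filters, kernel 7, stride 4; conv II 64
filters, kernel 5, stride 5; bottleneck D = 32 filters, kernel 3 — so
`T' = 50`. The desk-scale profile (`desk_profile()`) targets 250-sample
segments (250 ms at 1 kHz): 16/16 filters, kernels 9/5/3, strides 5/2,
D = 16, so `T' = 25`. During development we found that a wider desk-scale
bottleneck (D = 20, 24 filters) *reduced* downstream classification
accuracy despite better reconstruction — the classic bottleneck trade-off:
more capacity spends the code on carrier detail that the classifier must
then ignore.

# The classifier head

The frozen encoder's latent map feeds, in order: a feature-normalization
layer, one stride-1 temporal convolution with LeakyReLU, additive
self-attention pooling, a two-stage MLP, and a K-way softmax. The attention
scorer is the simplest mechanism matching "an importance score per time
step": `e_t = v' tanh(W h_t + b)`, weights `a = softmax(e)`, context
`c = sum_t a_t h_t`; the weights are returned for introspection. Argmax
ties break toward the lowest class index for determinism.

## Why feature standardization instead of within-sample layer norm

The normalization layer's purpose is to damp inter-trial and inter-subject
variance before classification. We first implemented it as conventional
layer normalization (each time step's feature vector standardized across
filters). That choice is actively harmful for this task and we replaced it:
per-time-step normalization erases the within-window activation envelope —
exactly the temporal structure that distinguishes movements — and cost
about six F1 points on the reference cohorts; normalizing each sample's
whole latent map likewise removes the gross contraction intensity, another
discriminative cue. The layer is therefore implemented as **latent feature
standardization**: each latent filter is z-scored with statistics fitted
once on the source-domain training latents (exactly like the input scaler,
and reused frozen for target-subject and expanded-class data), followed by
a learned per-filter affine. This removes dataset-level offset and scale
per feature — the stated inter-subject purpose — while preserving every
within-window cue. The statistics are buffers, bit-frozen through all
training stages.

Head training only ever updates head parameters; the encoder is copied into
the classifier and no training entry point touches it (bitwise-checked in
the tests). Because the encoder is frozen, latents are precomputed once per
partition, which makes head training cheap; `train_classifier()` optionally
trains several head initializations and keeps the best validation loss
(`n_restarts`), a cheap damper on initialization variance.

# Adaptation protocols

**Few-shot user calibration** (`few_shot_finetune()`): only the
highest-level decision layers — both MLP stages and the softmax output —
are trainable; encoder, normalization, temporal convolution, and attention
stay bit-frozen. "Final fully-connected layers" is read as *all* dense
stages rather than the output layer alone, because the adaptation is meant
to re-draw decision boundaries, not merely re-scale them. Calibration uses
the target subject's trial 1, validation trial 2, with the same optimizer
machinery.

**Incremental class expansion** (`expand_classes()` +
`two_phase_train()`): the K-unit output layer is removed and a freshly
initialized layer with one unit per expanded class is appended; the learned
weights and biases of every original class are copied into its
corresponding new unit. Because the features below are shared and frozen,
the original classes' pre-softmax logits are preserved *exactly* (asserted
with `expect_identical`). Phase I trains only the new output layer; the
best Phase-I checkpoint then enters Phase II, which unfreezes the whole
head (encoder still frozen) at a 10x lower learning rate — "significantly
lower" made concrete. A Phase II rate that is not lower triggers a
protocol-deviation warning but proceeds. `forgetting_report()` compares
per-class F1 on the original classes before and after expansion, scoring
the expanded model both with its full argmax and restricted to the original
output units, so stolen-by-new-class errors and genuine boundary drift are
visible separately.

# Evaluation

`prf1()` computes one-vs-rest precision, recall and F1 per class
(`P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; zero denominators
yield 0 with a flag) and a micro average from pooled counts — which, for
single-label multi-class prediction, equals accuracy (also asserted).
`cv_report()` aggregates folds into mean and standard error
(`sd / sqrt(n_folds)`). `confusion_flow()` reports the fraction of one
class's errors absorbed by another class — the tool used to localize
hierarchical ambiguity between base and combined movements after
expansion. `run_loso()` orchestrates the pooled, adaptation, and expansion
protocols per fold with per-fold seeds derived deterministically from the
global seed; `benchmark_methods()` runs the comparison pipelines on
identical folds and scalers; `model_cost_report()` derives parameter
counts, static bytes (4 bytes/parameter, the float32 deployment
convention), a peak-activation runtime estimate, and FLOPs per inference
(1 MAC = 2 FLOPs) purely from layer shapes.

# The synthetic cohort generator

Surface EMG during an isometric contraction is well approximated by
band-limited Gaussian noise whose amplitude follows the muscle activation
envelope. The generator realizes, per (subject, gesture, trial) and
channel:

```
gain_c(subject) * envelope_{g,c}(warped time) * carrier + noise_floor * white noise
```

* The **carrier** is white Gaussian noise band-passed in the frequency
  domain with raised-cosine edges (a zero-phase band-pass; >= 95% in-band
  power is a tested invariant) and rescaled to unit variance, drawn fresh
  per trial and channel.
* **Envelopes** are piecewise-linear profiles in [0, 1], optionally
  periodic, per gesture and channel. The default library codes each gesture
  redundantly by three physiologically motivated cues: which muscle
  dominates (per-channel levels on a quarter-circle arc), gross contraction
  intensity (alternating overall scale), and activation dynamics (deep
  triangular burst trains at a gesture-specific rate, 4–52 Hz, the two
  channels bursting in antiphase). The multi-cue design exists because a
  single-cue code is brittle: a cohort whose classes differed only in the
  two-channel variance ratio at near-constant total energy turned out to be
  nearly undecodable for conv-latent readouts while trivial for variance
  features — any realistic gesture set differs along several axes at once.
* **Inter-subject shift** is a per-channel log-normal gain plus a smooth
  sinusoidal warp of the envelope time axis, controlled by one scalar;
  0 makes subjects identical.
* Generation is seeded **per recording**, so a recording's content is
  independent of generation order and any sub-cohort is bit-reproducible.

What the generator does *not* emulate: motor-unit action potentials and
recruitment, fatigue, electrode shift, recording artifacts, or the
heavy-tailed amplitude statistics of real sEMG. Passing tests on these
cohorts therefore demonstrate that the pipeline's machinery — segmentation,
training, freezing, transfer, evaluation — behaves correctly and that the
architecture can exploit amplitude and temporal-envelope structure; they do
not certify accuracy levels on real recordings.

## Reference presets

* `easy6` — 6 gestures, 8 subjects, 6 trials of 5 s at 4 kHz, low subject
  shift (0.1): the well-separated base design.
* `shifted6` — as `easy6` with strong shift (0.8): a pooled model degrades
  on the held-out subject and calibration pays off.
* `easy10` — 10 gestures where gestures 7–10 superimpose the thumb
  envelope on gestures 3–6 (clipped sum): base/combined hierarchical
  ambiguity.
* `temporal2` — 2 classes, rising vs falling sawtooth envelope (two
  periods per analysis window); the falling profile is the exact time
  reversal of the rising one, so pooled amplitude distributions agree and
  only temporal order separates the classes. Representations that discard
  temporal structure (a flattened dense autoencoder) drop to chance here.

`reduced = TRUE` selects the desk-scale variants used throughout the test
suite and the acceptance script, sized for a single CPU: 1 kHz sampling
with a 20–200 Hz band (the band scales with Nyquist), 6 subjects with full
5 s trials for `easy6` (an absolute accuracy level is asserted there, which
needs training volume), and 4 subjects with 2.5 s trials for the
directional designs. The sparsity-sweep experiments use a still smaller
3-subject, 2.5 s cohort with the same gesture library. These sizes are the
package's desk-scale study conditions and are stated here once; the
full-scale presets keep the 8-subject 4 kHz protocol.

# Numerical choices and degenerate inputs

* Scaler and feature-normalization floors: `sd >= 1e-8`.
* Cross-entropy probability clamp: `1e-12`.
* Feature-normalization epsilon inherited from the scaler floor.
* Early stopping improves on `> 1e-9` validation-loss decrease; plateau
  scheduler halves the rate (floor `1e-5`).
* Argmax ties: lowest class index.
* Divergent training (non-finite loss) aborts with a diagnostic rather
  than returning garbage.
* Zero-variance batches make R-squared undefined: error, not NaN.

# Known limitations

* At desk scale, the two-phase expansion protocol's advantage over simply
  training the whole head directly on the expanded class set does not
  reproduce: direct training scores slightly higher here, so the staged
  protocol's benefit should be regarded as data- and scale-dependent. The
  protocol's structural guarantees (exact logit preservation at expansion,
  Phase II improving on Phase I) do hold and are tested.

* The NN engine is CPU-bound base R + small compiled kernels; it is sized
  for the desk-scale cohorts, not for GPU-scale experiments.
* `easy6` desk-scale pooled accuracy sits around 0.95–0.97 micro-F1;
  per-fold variation of +/- 0.02 across cohort seeds is normal at this
  data volume.
* The CNN-LSTM baseline trains end-to-end and is capacity-matched by total
  parameter count (+/- 20% warning), not by any finer notion of effective
  capacity.
* The generator's subject shift is a gain + time-warp abstraction; real
  electrode-shift and cross-talk phenomena are richer.
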