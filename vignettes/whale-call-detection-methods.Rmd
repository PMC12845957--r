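---
title: "Detecting humpback whale calls in short analysis windows: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting humpback whale calls in short analysis windows: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The detection problem

Passive acoustic monitoring produces continuous hydrophone audio in which
humpback vocalizations are sparse events embedded in a highly variable
soundscape: vessel machinery, snapping and clicking fauna, flow noise, and
broadband ambient sound. `whaledet` frames detection as binary
classification of short fixed windows. A 6-second window is long enough to
contain the harmonic, frequency-modulated structure of a call unit, and a
3-second hop means a deployed detector refreshes its decision every three
seconds while giving each event at least two chances to be seen.

All quantities downstream follow from three numbers fixed at design time:
the 22,050 Hz feature-extraction rate, the 6 s window (132,300 samples),
and the 50-frame spectrogram target, which forces the STFT hop to
132,300 / 50 = 2646 samples.

## Audio standardization

Ingested recordings vary in channel count, rate and level. `standardize()`
mixes channels by arithmetic mean, resamples to 44.1 kHz, and snaps
amplitudes once to the signed 16-bit grid (then holds floats thereafter, so
the operation is idempotent and integer arithmetic never propagates).
`resample()` works in the frequency domain: the signal is zero-padded to a
5-smooth length, its spectrum truncated or extended at the narrower Nyquist
(an ideal low-pass, hence anti-aliased by construction), and inverted; the
output length is `round(duration * target_rate)`, so duration is preserved
to within half an output sample. Padding to 5-smooth lengths keeps R's
mixed-radix FFT away from its quadratic worst case on prime lengths.

## Feature images

Both feature families share one STFT geometry: 2048-point FFT, periodic
Hann window, hop 2646, **no frame centering**. Centering (reflect-padding
half a window on each side) would produce 51 frames for a full window; with
centering disabled the frame-count identity
`1 + floor((132300 - 2048)/2646) = 50` is exact, which is the reason this
package never centers.

* **Mel spectrogram** — 125 triangular filters spaced on the mel scale
  (linear below 1 kHz, logarithmic above; area-normalized) spanning
  0–10 kHz, log-power scaled. dB values are referenced to the per-segment
  maximum with an 80 dB floor: the floor bounds the dynamic range a
  constant-silence segment would otherwise make infinite, and per-segment
  referencing makes the rendering invariant to absolute recording level.
* **Delta-MFCC** — an orthonormal DCT-II of the log-mel spectrum keeps the
  first `n_mfcc = 20` coefficients (the coefficient count is configurable;
  20 is the common speech/bioacoustics default), and the first-order delta
  is a Savitzky–Golay first derivative over a 9-frame window with a linear
  fit. This estimator returns exactly the slope for a linear cepstral
  trajectory — including at the edges — which makes its contract testable in
  closed form. The 20 × 50 delta matrix is linearly interpolated along the
  coefficient axis to 125 rows at render time; linear interpolation was
  chosen over replication so adjacent coefficient bands blend smoothly in
  the rendered image.

Rendering min–max scales each matrix to [0, 1] (affine-invariant; constant
matrices map to mid-scale 0.5 with no division by zero), passes values
through a perceptually uniform colormap (viridis by default, configurable —
the choice is aesthetic, as per-image standardization later removes
channel-wise affine structure), and fixes the orientation contract: row
index 1 is the lowest frequency. `standardize_image()` then removes the
per-image mean and divides by the per-image population standard deviation
(epsilon-guarded: constant images map to zeros). Standardization applies to
both classifier families; the in-memory pipeline keeps float images
throughout, with 8-bit PNG export available as an optional I/O path so that
training never quantizes twice.

## Source-based splitting

Windows from one recording overlap by 3 s and share recording-level
signatures (noise floor, gain, propagation). Randomly splitting *windows*
would therefore leak near-duplicates of training data into the test set and
inflate every metric. `assign_splits()` instead shuffles **source
identifiers** deterministically by seed and partitions them 70/15/15;
every window inherits its source's split. Split sizes round half away from
zero with the remainder assigned to train (20 sources → 14/3/3). The
pipeline applies the split *within each class* (stratified by label,
`stratify = TRUE`): with a few dozen sources, an unstratified shuffle can
hand the validation split a single class, and a validation set that one
degenerate always-one-class model classifies perfectly makes
validation-loss checkpointing meaningless. Stratification preserves the
source-level anti-leakage guarantee — it only constrains which *sources*
land where, never windows.
`check_no_leakage()` re-derives the invariant from any segment list and
manifest. Because source durations vary, class ratios drift across splits;
`cap_source()` truncates over-long recordings — the pipeline default caps
at the 95th percentile of per-source window counts, which limits
single-source dominance while discarding little data. Capping keeps the
temporal prefix rather than a random subset so results remain deterministic
and resumable.

## Augmentation

Training-split windows (only — the leakage guard refuses anything else)
pass through four waveform operators, each applied with independent
probability 0.5; the Bernoulli vector is redrawn whenever all four come up
empty, so no unaltered audio enters the augmented set. Conditional on
acceptance, each operator fires with probability
(1/2)/(1 − (1/2)⁴) = 8/15 ≈ 0.533 — an identity the test suite checks by
simulation.

* Gaussian noise with σ uniform in 1–1.5 % **of digital full scale** (1.0).
  The alternative reading — relative to the clip's own peak — would make
  augmentation strength depend on recording level; the full-scale
  convention is the one common in augmentation tooling, and is configurable.
* Pitch shift, uniform ±12 semitones, via phase vocoder (1024-point STFT,
  quarter-window hop, phase accumulation with wrapped deviation) followed by
  FFT resampling back to exactly 132,300 samples — the segment length is
  contractual, so the operator must be length-preserving.
* High-pass filter, cutoff uniform in 1–2 kHz, as a 4th-order Butterworth
  applied forward–backward (`filtfilt`, zero phase).
* Circular time shift, uniform ±3 s with rollover; a drawn shift that
  rounds to zero samples is redrawn, since it would violate the
  "no unaltered variant" guarantee on its own.

Operators apply in a fixed order (noise, pitch, high-pass, shift). Each
original window yields five variants; variant `i` of segment `s` is
reproducible from `(seed, s, i)` alone. Augmentation runs at 22,050 Hz on
already-windowed segments: augmenting before windowing would couple windows
through shared operator draws, and running at the feature rate halves the
cost of the most expensive operator. The pipeline trains on originals plus
variants by default (`include_originals = TRUE`), with the flag exposed
because the alternative (variants only) is an equally defensible reading of
"five variants per original".

## Classifier architectures

**CNN.** Four convolutional blocks — (16, 6×6, tanh), (32, 4×4, ReLU),
(64, 3×3, ReLU) each followed by 2×2 max-pooling, batch normalization and
dropout 0.5/0.4/0.3; then (64, 3×3) with flatten and dropout 0.2 — and a
dense-64 ReLU head with a 2-way softmax. Convolutions use "same" padding
and stride 1 (so the 125 × 50 grid only shrinks at pools: 62×25 → 31×12 →
15×6), pooling is 2×2/stride-2 (the common default where only
"MaxPooling2D" is specified), and the fourth convolution is linear with a
config switch, as no activation is specified for it. The first convolution
carries 16 × (6·6·3 + 1) = 1744 parameters — a closed-form identity the
tests assert against the built model.

**ViT.** 8×8 patches at stride 8 with VALID tiling drop the 5 remainder
rows and 2 remainder columns, leaving ⌊125/8⌋ × ⌊50/8⌋ = 15 × 6 = 90
tokens of 192 values. Tokens are linearly embedded to 64 dimensions and
given **learned** positional embeddings (the variant implied by
"supplemented with positional information" without a stated scheme), then
pass through 4 encoder blocks wired **pre-norm** with residual connections
(standard ViT practice; the block components were specified but not their
wiring): LayerNorm → 4-head attention (key dimension 64, dropout 0.1) →
residual; LayerNorm → MLP [128, 64] with GELU and dropout 0.1 → residual.
The head is global average pooling over tokens — implying no class token,
so none is used — followed by an MLP [2048, 1024] with GELU and dropout
0.3 and a 2-way softmax. With zeroed positional embeddings the pooled
logits are permutation-invariant in the patches; the test suite checks this
equivariance property directly.

All layers implement forward and backward passes natively (the convolution
hot path through compiled im2col + BLAS kernels); every gradient was
verified against central finite differences during development.

## Training

AdamW — Adam with decoupled weight decay 0.004 applied to kernel weights
(biases and normalization parameters are excluded, the customary choice) —
with base learning rate 10⁻³, batch size 128, and sparse categorical
cross-entropy.

Batch-norm inference statistics come from an explicit recalibration pass
("precise BN"): before each validation evaluation, and again after the best
checkpoint is restored, the network runs forward over the training images
with dropout inactive and the batch-norm layers re-estimate their
population mean and variance from those activations. The CNN interleaves
dropout between its convolutional blocks, so activations reaching a
batch-norm layer during training are systematically wider than at
inference (inverted dropout preserves means but inflates second moments);
a plain moving average of training-batch statistics therefore miscalibrates
eval-mode logits — badly so at this corpus scale, where a 10-epoch run
takes only tens of optimizer steps. Recalibration estimates the statistics
under exactly the distribution inference sees; a debiased moving average
remains as the fallback for models never recalibrated. The CNN trains 10 epochs at constant rate; the ViT trains up
to 30 epochs with a linear warm-up from 0 over the first 2 epochs (the ramp
start is unstated; 0 is the conventional choice) followed by cosine decay
to 0, early stopping with patience 5 on validation loss, and
best-validation-loss checkpointing with restoration. A configuration switch
allows either schedule on either architecture. Class imbalance is left
untreated beyond source capping — no class weights — matching the design
being reproduced. Reproducibility is best-effort bit-level within one
BLAS/R version: the seed governs initialization, shuffling and dropout.

## The synthetic corpus

No labeled field corpus ships with the package, so `synth_corpus()`
generates one with the statistical structure the pipeline assumes:

* **Calls** — units of 0.5–2 s with 150–800 Hz fundamentals, 2–4 harmonics
  at 1/h amplitude decay, geometric frequency sweeps up to ±1 octave,
  recurring with 0.5–2.5 s gaps (so a 6 s window contains a unit on
  average), over a pink-noise bed at 5–15 dB SNR.
* **No-call confounders** — pink noise; vessel-like tonals (25–150 Hz
  fundamental, 2–3 harmonics, slow 0.05–0.5 Hz amplitude modulation)
  mimicking the low-frequency machinery sounds that real detectors confuse
  with calls; and sparse band-limited clicks.

Defaults: 16 + 16 sources of 4–45 s (≈ 13 minutes of audio, ≈ 220 windows),
chosen so a full end-to-end run — synthesis, preparation, augmentation and
both trainings — completes in minutes on one CPU while still exercising
source-based splitting, truncation and the zero-window path for
sub-6-second files (one short no-call source is forced when the duration
range allows). The 5–15 dB SNR default makes the corpus a *high-SNR,
cleanly separable* regime: the held-out accuracy the acceptance run reports
on it is a pipeline correctness check, **not** evidence about field
performance. Real humpback song has richer unit grammar, propagation
effects, overlapping callers and label noise, none of which the generator
emulates; passing tests show the machinery is sound, not that the detector
is field-ready.

## Numerical choices and degenerate inputs

* dB floors at −80 dB below the per-segment maximum; digital silence maps
  to a constant matrix at the floor.
* Min–max rendering of a constant matrix yields mid-scale 0.5; per-image
  standardization of a constant image yields zeros (ε = 10⁻⁸ guard).
* MCC with a zero marginal is reported as 0 with a `degenerate` flag, and
  the report names both class-conditional error rates explicitly
  (`error_rate_humpback`, `error_rate_nocall`) rather than using FNR/FPR,
  whose orientation is ambiguous without a declared positive class.
* ROC thresholds are the distinct scores; ties contribute half their mass,
  making the trapezoidal area exactly the pairwise-concordance probability.
* Max-pooling gradient ties route to the first maximum in scan order;
  batch-norm uses ε = 10⁻³ and momentum 0.99; attention uses the scaled
  dot-product 1/√64.
* Pitch shifts smaller than 10⁻⁹ semitones return the input unchanged.

## Known limitations

The detector is binary; multi-class separation of confounder types is out
of scope. The transfer-learning path (`backbone_adapter()`) is a hook for
an externally supplied pretrained model and ships no weights. Training is
single-CPU by design; wall-clock scales linearly in windows × epochs.
Reported synthetic-corpus accuracies are conditional on the generator's
default regime; they are not field-performance estimates.
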