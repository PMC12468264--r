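---
title: "Joint mode decomposition and spatio-temporal classification of multichannel EEG"
author: "mvmdnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint mode decomposition and spatio-temporal classification of multichannel EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

### Multivariate variational mode decomposition

A C-channel signal $x(t) = [x_1(t), \dots, x_C(t)]$ is decomposed into
$K$ intrinsic mode functions $u_k(t) = [u_{k,1}(t), \dots, u_{k,C}(t)]$
that jointly minimize the summed bandwidth of their analytic signals
shifted to baseband, subject to per-channel reconstruction
$\sum_k u_{k,c} = x_c$. The crucial structural property is that each
mode index $k$ owns a **single center frequency $\omega_k$ shared by
all channels**, which guarantees cross-channel mode alignment — the
k-th component means the same thing on every channel. This is what
makes stacking per-mode spectrograms across channels coherent for a
downstream classifier.

The augmented Lagrangian (bandwidth penalty $\alpha$, per-channel
multipliers $\lambda_c$) is solved by ADMM in the frequency domain on
the discrete nonnegative-frequency grid:

1. **Mode update** (sequential in $k$, so mode $k{+}1$ already sees
   mode $k$'s new value):
   $\hat u_{k,c} \leftarrow \dfrac{\hat x_c - \sum_{i \ne k} \hat u_{i,c} + \hat\lambda_c / 2}{1 + 2\alpha(\omega - \omega_k)^2}$
2. **Center-frequency update**: $\omega_k$ becomes the power-weighted
   mean frequency of mode $k$'s spectra pooled over channels; an
   all-zero mode keeps its previous $\omega_k$ (division guard) with a
   warning.
3. **Dual ascent**:
   $\hat\lambda_c \leftarrow \hat\lambda_c + \tau(\hat x_c - \sum_k \hat u_{k,c})$.

Iteration stops when
$\sum_k \sum_c \|\Delta \hat u_{k,c}\|^2 / \|\hat u_{k,c}\|^2 < \epsilon$
or at `maxIter`. The statistic's first value compares against the
all-zero start, where the zero-norm guard zeroes every term, so
convergence is only honoured from iteration 2.

**Assumptions.** The signal is well described by a small number of
narrow-band, amplitude/frequency-modulated oscillators that are
*shared* across channels (possibly with different amplitudes and
phases). Broadband transients are split across modes; strongly
channel-specific oscillators violate the shared-$\omega_k$ premise and
are averaged into the nearest common mode.

### Decomposition parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `K` | task-specific (4 for the 2-channel pair task, 8 for the 7-channel scalp task) | modes | study configuration; `K < N/2` required |
| `alpha` | 2000 | dimensionless | study configuration; larger = narrower modes |
| `tau` | 0 | dimensionless | disables exact-reconstruction enforcement, which is more robust under additive noise; any `tau > 0` re-enables the dual ascent |
| `tol` | 1e-7 | relative change | tone fixtures converge in tens of iterations |
| `maxIter` | 500 | iterations | cap; result is still returned (flagged unconverged) |
| `init` | `"uniform"` | — | K starting frequencies evenly inside (0, 0.5) cycles/sample; deterministic and standard; `"zero"` and seeded `"random"` available |
| `mirrorExtend` | `TRUE` | — | symmetric extension by N/2 per side before the transform |

### Numerical choices

* **Grid.** Nonnegative DFT bins $0 \dots \lfloor T/2 \rfloor$ of the
  (possibly extended) length-$T$ signal; all integrals are sums on this
  grid. Time-domain modes come from conjugate-symmetric extension of
  the half spectra and the real part of the inverse FFT.
* **Two-phase synthesis.** Mirror extension stabilizes bandwidth and
  center-frequency estimation, but the Wiener filter discards the
  broadband leakage of the mirror junctions, which corrupts the first
  and last samples after trimming. The solver therefore estimates
  $\omega_k$ on the extended grid and then re-synthesizes the final
  modes on the original support with the converged frequencies held
  fixed (same fixed-point iteration, frequency updates off). On the
  noiseless two-tone fixture this reduces the relative reconstruction
  error from ~6% (dominated entirely by the two edges) to ~1e-6.
* **Ordering.** Modes are sorted by ascending center frequency after
  convergence; the stable sort keeps the original index on ties.
* **Degenerate inputs.** A zero signal yields zero modes with the
  initial (ascending) frequencies; an all-zero mode spectrum freezes
  its $\omega_k$ rather than producing NaN. `K >= N/2` and non-finite
  samples are rejected up front.
* **No DC mode.** Near-DC energy is expected to be removed upstream by
  the 0.5 Hz band-pass corner; the decomposition reserves no mode for
  DC.

### Preprocessing

Offline EEG practice: a quality-factor-30 biquad notch at the
power-line frequency (50 or 60 Hz) and a 4th-order Butterworth
band-pass (0.5–50 Hz), both applied forward–backward so the filters are
zero-phase. Epochs are non-overlapping one-second cuts
(`epochSegment`); under-represented classes can be oversampled with
sliding windows (`slidingWindowAugment`, default 50% overlap — the
procedure is standard, the step size is this package's choice). Channel
selection (`selectChannels`) matches labels case-insensitively and
tolerates montage decorations (`EEG FP1-REF` resolves `FP1`); raw
labeled channels are used rather than bipolar derivations, since the
recordings of interest list plain electrode names.

### Spectrogram features

Per (channel, mode) series: Hann window, hop `nperseg - overlap`, each
frame zero-padded to `nfft` before the DFT, **magnitude** (not power)
retained. Two deliberate dialect choices make the geometry exact for
both study configurations:

* `nfft = fs` gives 1 Hz bin spacing, so the inclusive 0–50 Hz crop
  keeps exactly 51 bins at both 512 Hz (nperseg 128) and 256 Hz
  (nperseg 64);
* zero boundary padding by `nperseg/2` at both ends gives
  `N/hop + 1 = 9` frames for a one-second epoch at both rates.

Slices are stacked channel-major (all K modes of channel 1 first) into
the (K·C) × F × T tensor: (8, 51, 9) for the two-channel pair task and
(56, 51, 9) for the seven-channel scalp task. The tensor holds raw
magnitudes; optional z-scoring is applied at batch assembly
(`featuresToArray(normalize = TRUE)`) so the container's nonnegativity
invariant stays meaningful.

### The classifier

Stages, with the study-scale shapes for the pair task:

1. **Convolution block**: one 3×3 convolution (padding 1, stride 1)
   with `convFilters` output maps, batch normalization, ReLU, adaptive
   average pooling onto a 6×6 grid of near-equal cells → (16, 6, 6).
2. **Maps to sequence**: the pooled *time* axis becomes the step axis;
   each step stacks (filter, pooled-frequency) pairs filter-major
   → 6 steps × 96 features. (Which pooled axis becomes the sequence is
   not dictated by the architecture; time is the natural choice and is
   fixed here.)
3. **BiGRU**: two stacked bidirectional layers, hidden size 512 per
   direction, outputs concatenated per step → (6, 1024). The GRU
   follows the printed gate equations: update gate
   $z = \sigma(W_z[h, x])$, reset gate $r = \sigma(W_r[h, x])$,
   candidate $\tilde h = \tanh(W_h[r * h, x])$ (reset applied to the
   state *before* the linear map), and
   $h_t = (1 - z) * h_{t-1} + z * \tilde h$ — a larger update gate
   admits *more* new information, the mirror image of some library
   conventions.
4. **Tokens**: row-major re-chunking into 128-wide tokens → (48, 128);
   a learned class token (zero-init plus 0.02-sd noise) is prepended
   and sinusoidal positions
   $PE(pos, 2i) = \sin(pos / 10000^{2i/d})$,
   $PE(pos, 2i{+}1) = \cos(\cdot)$ are added to every token including
   the class token → (49, 128).
5. **Transformer encoder**: 3 post-norm layers (self-attention with 8
   heads + position-wise feed-forward, internal residuals and layer
   norms), feed-forward width `4 * tokenDim` by default → (49, 128).
6. **Head**: dense map from the class-token embedding to the class
   logits; softmax for probabilities.

**Residual placement** (the architecture names the skips but not their
endpoints): a linearly projected copy of the BiGRU *input* is added to
its output, and the encoder *input sequence* (class token included) is
added to the encoder output. Both are controlled by `useResidual`.

**Ablation switches.** `useCNN = FALSE` adaptive-pools the raw tensor
and linearly projects each step to the convolution stage's feature
width; `useBiGRU = FALSE` replaces the recurrent stage with a per-step
linear projection to 2·`gruHidden`; `useTransformer = FALSE` bypasses
the encoder (token width is unchanged) and classification reads the
*mean of the non-class tokens*, because an untouched learned class
token carries no input information. Every variant is constructible and
trains.

**Engine.** No deep-learning runtime is assumed: forward and backward
passes are dense matrix code (convolution via im2col + BLAS, BPTT
through the GRU variant above, standard softmax/layer-norm/attention
backward rules). The full composite gradient is validated against
central finite differences in the test suite (tolerance 1e-5 on a
small configuration). Batch normalization uses biased batch variance
in training and running statistics (momentum 0.1) in evaluation.
Dropout defaults to 0 (the architecture description names none); the
configuration hook applies inverted dropout inside the encoder
sub-blocks when set.

### Training and evaluation

Adam (β₁ 0.9, β₂ 0.999) at initial learning rate 1e-3, multiplied by
0.1 every 5 epochs — as printed, this drives the rate to ~1e-41 by
epoch 200, i.e. effectively freezes the model after roughly epoch 40;
an optional `lrFloor` stops the decay but is off by default to match
the printed schedule. Cross-entropy loss, batch size 64 at study scale.
Runs are bit-reproducible: weights are seeded at construction and the
only training randomness is the seeded shuffle.

Metrics: accuracy; for two-class tasks sensitivity = recall of the
positive (focal/seizure) class and specificity = recall of the other
class — the positive anchoring is a package convention, fixed for
reproducibility; class-frequency-weighted F1; confusion matrices in
counts and row-normalized form. Multi-class reports carry accuracy,
weighted F1 and per-class recalls (sensitivity/specificity are `NA`).

Two protocols: `makeEpochFolds` (stratified epoch-level k-fold, the
subject-dependent setting; whether the original five-fold split was
patient-aware is not documented, so plain stratification is used) and
`makeSubjectFolds` (patient-level folds, greedy size balancing with a
seeded shuffle; no patient ever contributes to two folds — the
subject-independent setting).

## What the synthetic generators emulate — and what they do not

`genMultichannelTones` produces the structure MVMD assumes: a small set
of narrow-band oscillators *shared across channels* with
channel-specific amplitudes/phases, optional amplitude modulation,
plus white (or 1/f-shaped) Gaussian noise calibrated to a requested
SNR over the whole epoch. Ground-truth components are returned, and
components + noise reproduce the signal exactly, so recovery can be
scored without circularity.

`genClassificationSet` produces spectrally separable classes (default:
8–12 Hz continuous activity vs 18–25 Hz bursts; a six-band,
seven-channel variant mimics the multi-class task shape). The bands are
disjoint *by construction* — a plain band-power discriminant already
separates them — so these fixtures test that the pipeline can learn an
honest, learnable signal, not that it rivals clinical performance.

Real EEG differs in ways the fixtures deliberately omit: 1/f background
with nonstationary band power, artifacts (blinks, EMG, electrode pops),
inter-subject variability, volume-conduction correlations, and class
overlap. Passing the desk-scale tests therefore demonstrates
correctness of the machinery (decomposition, features, learning,
protocols), not expected accuracy on clinical recordings, which are not
redistributable with this package.

## Desk-scale problem sizes

The examples, tests and acceptance script run on one CPU in minutes by
choosing small study conditions — these are the package's documented
defaults for its own verification, not statements about the original
experiments: 128 Hz two-channel fixtures (the spectrogram geometry is
checked at the full 512/256 Hz rates), 100 epochs per class, K = 2
modes, a reduced classifier (8 filters, pool 3, hidden 16, token width
16, 1 encoder layer) and 10 training epochs with batch 16. The
study-scale configurations (16/128 filters, pool 6, hidden 512, token
width 128, 3 encoder layers, batch 64, 200 epochs) are exercised for
shape correctness in the forward direction.

## Known limitations

* No artifact rejection, re-referencing beyond channel pick-out, or
  resampling (a sampling-rate mismatch on EDF input is an explicit
  error).
* The pure-R training engine is sized for desk-scale experiments;
  study-scale training (thousands of epochs, hidden size 512) is out of
  its intended range.
* `K` is fixed by the user; there is no adaptive mode-count selection.
* The EDF reader covers continuous recordings with identical sampling
  rates across requested channels — enough for round-tripping test
  recordings and reading plain continuous files, not a full clinical
  EDF+ implementation.
* Seizure-type labels for multi-class work are expected as a manifest
  file; no annotation-format parser is included.
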