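# mvmdnet

Joint mode decomposition and spatio-temporal neural classification of
multichannel EEG, in R.

## The problem

Epileptic EEG classification — separating focal from non-focal
intracranial signals, or distinguishing seizure types on scalp EEG —
works best when the raw multichannel signal is first decomposed into
narrow-band oscillatory components. Channel-by-channel decompositions
(EMD, single-channel VMD) suffer from *mode mismatch*: the k-th
component of one channel need not live at the same frequency as the
k-th component of another, which scrambles any downstream learner that
stacks components across channels.

**Multivariate variational mode decomposition (MVMD)** fixes this by
decomposing all C channels jointly. It extracts K intrinsic mode
functions (IMFs) u_k(t) = [u_{k,1}(t), …, u_{k,C}(t)] with **one shared
center frequency ω_k per mode**, solving

    minimize_{u_k, ω_k}  Σ_k Σ_c ‖ ∂_t [ u⁺_{k,c}(t) e^{-jω_k t} ] ‖²
    subject to           Σ_k u_{k,c}(t) = x_c(t),   c = 1 … C

where u⁺ is the analytic signal (unilateral spectrum). The augmented
Lagrangian (bandwidth penalty α, multipliers λ_c) is solved by ADMM in
the frequency domain, alternating

* a sequential Wiener-filter mode update
  û_k ← (x̂ − Σ_{i≠k} û_i + λ̂/2) / (1 + 2α(ω − ω_k)²),
* the power-weighted center-frequency update
  ω_k ← Σ_c ∫ ω |û_{k,c}|² dω / Σ_c ∫ |û_{k,c}|² dω,
* dual ascent λ_c ← λ_c + τ (x̂_c − Σ_k û_{k,c}),

until the relative change Σ_k Σ_c ‖Δû_{k,c}‖²/‖û_{k,c}‖² falls below a
tolerance ϵ.

Each IMF is then turned into a short-time Fourier magnitude spectrogram
(Hann window), the (K·C) spectrograms are stacked into a tensor, and a
**CNN → BiGRU → Transformer-encoder** classifier reads it: a
convolution block captures local spectro-temporal patterns, a
bidirectional GRU captures short-range temporal dependencies, a learned
CLS token plus sinusoidal positions and a self-attention encoder
capture long-range structure, and a dense head classifies the CLS
embedding. Residual skips wrap the recurrent and encoder stages, and
every stage has an ablation switch.

The package implements the whole chain — preprocessing (notch +
band-pass filtering, epoching, sliding-window augmentation, channel
selection), the MVMD solver, the feature stage, the classifier with its
own training loop (Adam, step learning-rate schedule, cross-entropy),
epoch-level stratified and patient-level subject-independent
cross-validation, metric reports, synthetic fixture generators, and
readers for two-column ASCII signal pairs and EDF recordings — with no
external deep-learning runtime: the network forward/backward passes are
dense matrix code validated by finite-difference gradient checks.

## Worked example

```r
library(mvmdnet)

# two channels sharing 10 Hz and 25 Hz oscillators, 20 dB SNR
fixture <- genMultichannelTones(
  toneSpec(freqs = c(10, 25), channels = 2, fs = 128, duration = 4,
           snrDb = 20, seed = 7))

modes <- mvmdDecompose(fixture$signal, mvmdConfig(K = 2))
modes
#> ModeSet: K=2 modes x 2 channel(s) x 512 samples @ 128 Hz
#>  center frequencies (Hz): 9.997, 25
#>  converged after 11 iterations (final relative change 6.26e-09)
```

The two shared center frequencies are recovered to within 0.003 Hz of
the ground truth despite the additive noise, and both channels' k-th
modes sit at the same frequency by construction.

```r
feats <- buildFeatureTensor(modes, stftConfig(nperseg = 32, overlap = 16))
feats
#> FeatureTensor: (4, 51, 33) [(K*C) x freq x time]
#>  freq 0-50 Hz (51 bins), time 0-4 s (33 frames)
```

The first axis enumerates (channel, mode) pairs channel-major — K·C = 4
spectrograms of 51 frequency bins (1 Hz spacing, 0–50 Hz kept) by 33
frames. A desk-scale, end-to-end classification run on the synthetic
two-class fixture (8–12 Hz epochs vs 18–25 Hz bursts):

```r
set <- genClassificationSet(classSpec(nEpochs = 30, channels = 2,
                                      fs = 128, seed = 11))
ds <- featurizeEpochs(set$epochs, set$labels, mvmdConfig(K = 2),
                      stftConfig(nperseg = 32, overlap = 16),
                      normalize = TRUE)
model <- buildModel(modelConfig(inMaps = 4, nClasses = 2, convFilters = 8,
                                poolOut = 3, gruHidden = 16, tokenDim = 16,
                                nHeads = 2, encoderLayers = 1), seed = 5)
fit <- trainModel(model, ds, trainConfig(batchSize = 16, epochs = 10,
                                         lr = 1e-3, seed = 5))
evaluateModel(fit$model, ds)
#> EvalReport
#>  ACC 100.00%  SEN 100.00%  SPE 100.00%  weighted F1 1.000
#>  confusion (rows = true):
#>     pred
#> true  1  2
#>    1 30  0
#>    2  0 30
```

ACC/SEN/SPE are percentages (SEN = recall of the positive class, SPE =
recall of the negative class); weighted F1 is the class-frequency-
weighted mean of per-class F1 scores. `crossValidate()` wraps the same
loop in stratified 5-fold (subject-dependent) or patient-disjoint
3-fold (subject-independent) protocols.

A command-line front end over the same functions lives in
`inst/cli/mvmdnet.R`:

```sh
Rscript inst/cli/mvmdnet.R simulate --out data --classes 2 --fs 128 --seed 3
Rscript inst/cli/mvmdnet.R featurize --manifest data/manifest.csv --fs 128 --k 2 --out feat.rds
Rscript inst/cli/mvmdnet.R train --features feat.rds --out model.rds --epochs 10
Rscript inst/cli/mvmdnet.R evaluate --features feat.rds --model model.rds --out results/eval
```

Every stage writes a YAML log with its configuration and seeds.

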