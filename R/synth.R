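#' Specification for a multichannel tone fixture
#'
#' Describes a synthetic signal in which every channel carries the same
#' set of narrow-band oscillators (shared frequencies, channel-specific
#' amplitudes and phases) plus additive noise — the structure a joint
#' mode decomposition assumes. Ground-truth component series are
#' returned by the generator so recovery can be scored exactly.
#'
#' @param freqs component frequencies in Hz (all below `fs/2`).
#' @param channels number of channels C.
#' @param fs sampling rate in Hz.
#' @param duration length in seconds.
#' @param amps C x J amplitude matrix (default all 1).
#' @param phases C x J phase matrix in radians (default: drawn uniformly
#'   from the seed).
#' @param amDepth amplitude-modulation depth in [0, 1) applied to every
#'   component (0 = pure tones).
#' @param amFreq amplitude-modulation frequency in Hz.
#' @param snrDb signal-to-noise ratio of the additive Gaussian noise in
#'   dB over the whole epoch, per channel; `Inf` disables noise.
#' @param noise `"white"` or `"pink"` (1/f-shaped) noise.
#' @param seed RNG seed; recorded in the spec.
#' @return a list of class `"ToneSpec"`.
#' @export
toneSpec <- function(freqs, channels = 2L, fs = 128, duration = 4,
                     amps = NULL, phases = NULL, amDepth = 0, amFreq = 1,
                     snrDb = Inf, noise = c("white", "pink"), seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(all(freqs > 0), all(freqs < fs / 2), channels >= 1,
            duration > 0, amDepth >= 0, amDepth < 1, !is.na(snrDb))
  J <- length(freqs)
  if (is.null(amps)) amps <- matrix(1, channels, J)
  if (!is.null(phases)) stopifnot(dim(phases) == c(channels, J))
  stopifnot(dim(amps) == c(channels, J))
  structure(list(freqs = freqs, channels = as.integer(channels), fs = fs,
                 duration = duration, amps = amps, phases = phases,
                 amDepth = amDepth, amFreq = amFreq, snrDb = snrDb,
                 noise = noise, seed = as.integer(seed)),
            class = "ToneSpec")
}

pinkNoise <- function(n) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))                  # avoid dividing DC by 0
  f <- pmin(f, n - f + 1)                    # symmetric shaping
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Generate a multichannel tone fixture with ground truth
#'
#' Each channel c is
#' `sum_j a[c,j] * cos(2*pi*f_j*t + phi[c,j]) * (1 + am)` plus calibrated
#' noise. The per-component series and the noise are returned so that
#' `colSums(components) + noise == signal` holds exactly and center-
#' frequency recovery can be scored against the true `freqs`.
#'
#' @param spec a [toneSpec()].
#' @return list with `signal` (a [MultichannelSignal-class]),
#'   `components` (array J x C x N, ground truth per component) and
#'   `noise` (C x N matrix).
#' @export
genMultichannelTones <- function(spec) {
  stopifnot(inherits(spec, "ToneSpec"))
  withSeed(spec$seed, {
    N <- as.integer(round(spec$fs * spec$duration))
    t <- (seq_len(N) - 1) / spec$fs
    C <- spec$channels
    J <- length(spec$freqs)
    phases <- spec$phases
    if (is.null(phases))
      phases <- matrix(stats::runif(C * J, 0, 2 * pi), C, J)
    am <- if (spec$amDepth > 0)
      1 + spec$amDepth * sin(2 * pi * spec$amFreq * t) else rep(1, N)
    comps <- array(0, c(J, C, N))
    for (j in seq_len(J)) for (cc in seq_len(C))
      comps[j, cc, ] <- spec$amps[cc, j] *
        cos(2 * pi * spec$freqs[j] * t + phases[cc, j]) * am
    clean <- apply(comps, c(2L, 3L), sum)
    if (J == 1L) clean <- matrix(clean, nrow = C)
    noise <- matrix(0, C, N)
    if (is.finite(spec$snrDb)) {
      for (cc in seq_len(C)) {
        raw <- if (spec$noise == "white") stats::rnorm(N) else pinkNoise(N)
        sigma <- sqrt(mean(clean[cc, ]^2) / 10^(spec$snrDb / 10))
        noise[cc, ] <- sigma * raw / stats::sd(raw)
      }
    }
    list(signal = multichannelSignal(clean + noise, spec$fs),
         components = comps, noise = noise)
  })
}

#' Specification for a labeled classification fixture
#'
#' Defines spectrally separable classes: every epoch of class `i` carries
#' oscillatory energy inside band `i` (center +/- width/2), optionally as
#' bursts, plus additive noise. Bands should not overlap so a band-power
#' discriminant can separate the classes by construction.
#'
#' @param bands data.frame with columns `center` (Hz), `width` (Hz) and
#'   optionally `burstRate` (bursts per second; 0 = continuous), one row
#'   per class. Defaults to two well-separated EEG-like bands
#'   (8--12 Hz continuous vs 18--25 Hz bursts).
#' @param nEpochs epochs per class.
#' @param channels channels per epoch.
#' @param fs sampling rate in Hz.
#' @param epochSeconds epoch duration.
#' @param tonesPerEpoch number of random tones drawn inside the class
#'   band per epoch.
#' @param snrDb additive white-noise level in dB.
#' @param seed RNG seed.
#' @return a list of class `"ClassSpec"`.
#' @export
classSpec <- function(bands = NULL, nEpochs = 100L, channels = 2L,
                      fs = 512, epochSeconds = 1, tonesPerEpoch = 3L,
                      snrDb = 10, seed = 1L) {
  if (is.null(bands))
    bands <- data.frame(center = c(10, 21.5), width = c(4, 7),
                        burstRate = c(0, 2))
  if (is.null(bands$burstRate)) bands$burstRate <- 0
  stopifnot(nrow(bands) >= 2, all(bands$center + bands$width / 2 < fs / 2))
  lo <- bands$center - bands$width / 2
  hi <- bands$center + bands$width / 2
  ord <- order(lo)
  if (any(hi[ord][-length(ord)] > lo[ord][-1L]))
    stop("class bands overlap; classes must be separable by construction")
  structure(list(bands = bands, nEpochs = as.integer(nEpochs),
                 channels = as.integer(channels), fs = fs,
                 epochSeconds = epochSeconds,
                 tonesPerEpoch = as.integer(tonesPerEpoch), snrDb = snrDb,
                 seed = as.integer(seed)),
            class = "ClassSpec")
}

#' Six-band specification shaped like the multi-class scalp-EEG task
#'
#' Convenience wrapper: six disjoint bands, seven channels, 256 Hz.
#'
#' @param nEpochs epochs per class.
#' @param seed RNG seed.
#' @return a [classSpec()].
#' @export
classSpec6 <- function(nEpochs = 50L, seed = 1L) {
  classSpec(bands = data.frame(center = c(3, 7, 12, 18, 26, 38),
                               width = c(2, 2, 3, 4, 6, 8),
                               burstRate = c(0, 0, 0, 2, 2, 4)),
            nEpochs = nEpochs, channels = 7L, fs = 256, seed = seed)
}

#' Generate a labeled set of spectrally separable epochs
#'
#' Produces `nrow(bands) * nEpochs` one-epoch
#' [MultichannelSignal-class] objects with balanced class labels. Each
#' epoch sums `tonesPerEpoch` random tones inside its class band (random
#' per-channel phases, random amplitudes in [0.5, 1.5]), gated into
#' bursts when the class `burstRate` is positive, plus white noise at
#' `snrDb`.
#'
#' @param spec a [classSpec()].
#' @return list with `epochs` (list of signals), `labels` (integer
#'   1..nClasses) and `bands`.
#' @export
genClassificationSet <- function(spec) {
  stopifnot(inherits(spec, "ClassSpec"))
  nClasses <- nrow(spec$bands)
  withSeed(spec$seed, {
    N <- as.integer(round(spec$fs * spec$epochSeconds))
    t <- (seq_len(N) - 1) / spec$fs
    epochs <- vector("list", nClasses * spec$nEpochs)
    labels <- integer(length(epochs))
    i <- 0L
    for (cl in seq_len(nClasses)) {
      b <- spec$bands[cl, ]
      env <- if (b$burstRate > 0)
        as.numeric(sin(2 * pi * b$burstRate * t) > 0) else rep(1, N)
      for (e in seq_len(spec$nEpochs)) {
        i <- i + 1L
        x <- matrix(0, spec$channels, N)
        for (j in seq_len(spec$tonesPerEpoch)) {
          f <- stats::runif(1, b$center - b$width / 2, b$center + b$width / 2)
          for (cc in seq_len(spec$channels)) {
            a <- stats::runif(1, 0.5, 1.5)
            ph <- stats::runif(1, 0, 2 * pi)
            x[cc, ] <- x[cc, ] + a * cos(2 * pi * f * t + ph)
          }
        }
        x <- x * rep(env, each = spec$channels)
        for (cc in seq_len(spec$channels)) {
          sigma <- sqrt(max(mean(x[cc, ]^2), 1e-12) / 10^(spec$snrDb / 10))
          x[cc, ] <- x[cc, ] + stats::rnorm(N, 0, sigma)
        }
        epochs[[i]] <- multichannelSignal(x, spec$fs)
        labels[i] <- cl
      }
    }
    list(epochs = epochs, labels = labels, bands = spec$bands)
  })
}

#' Featurize a list of epochs for classification
#'
#' Decomposes every epoch with MVMD and stacks the band-cropped
#' spectrogram tensors into a training-ready dataset.
#'
#' @param epochs list of [MultichannelSignal-class] epochs.
#' @param labels integer labels (1..nClasses), one per epoch.
#' @param mvmdCfg an [mvmdConfig()].
#' @param stftCfg an [stftConfig()].
#' @param normalize z-score the assembled batch (see
#'   [featuresToArray()]).
#' @return list with `x` (array F x T x maps x n) and `y` (labels).
#' @export
featurizeEpochs <- function(epochs, labels, mvmdCfg, stftCfg,
                            normalize = FALSE) {
  stopifnot(length(epochs) == length(labels))
  tensors <- lapply(epochs, epochFeatures, mvmdCfg = mvmdCfg,
                    stftCfg = stftCfg)
  list(x = featuresToArray(tensors, normalize = normalize),
       y = as.integer(labels))
}
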