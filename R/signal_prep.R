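#' Preprocessing configuration
#'
#' Filtering and epoching settings applied ahead of the decomposition:
#' a power-line notch (50 Hz in Europe, 60 Hz in North America) followed
#' by a 0.5--50 Hz band-pass, then segmentation into fixed-length epochs.
#'
#' @param notchHz power-line frequency to suppress, Hz.
#' @param notchQ notch quality factor (center frequency / -3 dB width).
#' @param bandLow,bandHigh band-pass corner frequencies, Hz.
#' @param filterOrder Butterworth prototype order.
#' @param epochSeconds epoch duration in seconds.
#' @param zeroPhase apply filters forward-backward (no group delay).
#' @param overlapFraction sliding-window overlap used for augmentation.
#' @param seed seed recorded for any randomized epoch selection.
#' @return a list of class `"PreprocessConfig"`.
#' @export
preprocessConfig <- function(notchHz = 50, notchQ = 30, bandLow = 0.5,
                             bandHigh = 50, filterOrder = 4,
                             epochSeconds = 1, zeroPhase = TRUE,
                             overlapFraction = 0.5, seed = NULL) {
  stopifnot(notchHz > 0, notchQ > 0, bandLow > 0, bandLow < bandHigh,
            filterOrder >= 1, epochSeconds > 0,
            overlapFraction >= 0, overlapFraction < 1)
  structure(list(notchHz = notchHz, notchQ = notchQ, bandLow = bandLow,
                 bandHigh = bandHigh, filterOrder = as.integer(filterOrder),
                 epochSeconds = epochSeconds, zeroPhase = isTRUE(zeroPhase),
                 overlapFraction = overlapFraction, seed = seed),
            class = "PreprocessConfig")
}

applyFilterRows <- function(x, b, a, zeroPhase) {
  out <- x
  for (i in seq_len(nrow(x))) {
    out[i, ] <- if (zeroPhase)
      as.numeric(signal::filtfilt(b, a, x[i, ]))
    else
      as.numeric(signal::filter(b, a, x[i, ]))
  }
  out
}

#' Power-line notch filter
#'
#' Second-order IIR notch (constrained biquad) at `f0` with quality
#' factor `q`, applied forward-backward for zero phase. Attenuation at
#' the notch frequency exceeds 20 dB on a pure-tone probe; the passband
#' away from `f0` is essentially untouched.
#'
#' @param signal a [MultichannelSignal-class].
#' @param f0 notch frequency in Hz, must be below Nyquist.
#' @param q quality factor.
#' @param zeroPhase forward-backward application.
#' @return the filtered [MultichannelSignal-class], same shape.
#' @export
notchFilter <- function(signal, f0, q = 30, zeroPhase = TRUE) {
  stopifnot(is(signal, "MultichannelSignal"))
  fs <- samplingRate(signal)
  if (f0 >= fs / 2) stop("notch frequency must be below Nyquist (fs/2)")
  w0 <- 2 * pi * f0 / fs
  aq <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + aq)
  a <- c(1, -2 * cos(w0) / (1 + aq), (1 - aq) / (1 + aq))
  multichannelSignal(applyFilterRows(samples(signal), b, a, zeroPhase),
                     fs, channelNames(signal))
}

#' Band-pass filter
#'
#' Butterworth band-pass (default 4th-order prototype) between `low` and
#' `high` Hz, applied forward-backward by default so no group delay is
#' introduced. Out-of-band tones are attenuated by well over 20 dB; DC
#' offsets are removed.
#'
#' @param signal a [MultichannelSignal-class].
#' @param low,high corner frequencies in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth prototype order.
#' @param zeroPhase forward-backward application.
#' @return the filtered [MultichannelSignal-class], same shape.
#' @export
bandpassFilter <- function(signal, low, high, order = 4, zeroPhase = TRUE) {
  stopifnot(is(signal, "MultichannelSignal"))
  fs <- samplingRate(signal)
  if (!(low > 0 && low < high && high < fs / 2))
    stop("invalid band: need 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  multichannelSignal(applyFilterRows(samples(signal), bf$b, bf$a, zeroPhase),
                     fs, channelNames(signal))
}

#' Apply the standard preprocessing chain
#'
#' Notch filter followed by band-pass filter, per the configuration.
#'
#' @param signal a [MultichannelSignal-class].
#' @param cfg a [preprocessConfig()].
#' @return the filtered [MultichannelSignal-class].
#' @export
preprocess <- function(signal, cfg = preprocessConfig()) {
  stopifnot(inherits(cfg, "PreprocessConfig"))
  out <- notchFilter(signal, cfg$notchHz, cfg$notchQ, cfg$zeroPhase)
  bandpassFilter(out, cfg$bandLow, cfg$bandHigh, cfg$filterOrder,
                 cfg$zeroPhase)
}

#' Segment a recording into non-overlapping epochs
#'
#' Cuts consecutive epochs of exactly `epochSeconds * fs` samples; a
#' trailing partial epoch is discarded. Returns
#' `floor(N / (epochSeconds * fs))` epochs.
#'
#' @param signal a [MultichannelSignal-class].
#' @param epochSeconds epoch duration in seconds; `epochSeconds * fs`
#'   must be integral.
#' @return list of [MultichannelSignal-class] epochs (empty, with a
#'   warning, if the recording is shorter than one epoch).
#' @export
epochSegment <- function(signal, epochSeconds = 1) {
  stopifnot(is(signal, "MultichannelSignal"), epochSeconds > 0)
  fs <- samplingRate(signal)
  nper <- epochSeconds * fs
  if (abs(nper - round(nper)) > 1e-9)
    stop("epochSeconds * fs must be an integer number of samples")
  nper <- as.integer(round(nper))
  N <- nTimepoints(signal)
  nEpochs <- N %/% nper
  if (nEpochs == 0L) {
    warning("signal shorter than one epoch; returning no epochs")
    return(list())
  }
  x <- samples(signal)
  lapply(seq_len(nEpochs), function(i) {
    multichannelSignal(x[, ((i - 1L) * nper + 1L):(i * nper), drop = FALSE],
                       fs, channelNames(signal))
  })
}

#' Overlapping sliding-window augmentation
#'
#' Extracts epochs whose start points advance by
#' `epochLength * (1 - overlapFraction)` samples, stopping at `quota`
#' windows or the end of the signal. With `overlapFraction = 0` this
#' reduces to plain segmentation. Used to oversample under-represented
#' classes (e.g. rare seizure types).
#'
#' @param signal a [MultichannelSignal-class].
#' @param epochSeconds epoch duration in seconds.
#' @param overlapFraction fraction of each window shared with the next,
#'   in [0, 1).
#' @param quota maximum number of windows to return (> 0; `Inf` for all).
#' @return list of [MultichannelSignal-class] epochs.
#' @export
slidingWindowAugment <- function(signal, epochSeconds = 1,
                                 overlapFraction = 0.5, quota = Inf) {
  stopifnot(is(signal, "MultichannelSignal"),
            overlapFraction >= 0, overlapFraction < 1)
  if (!(quota > 0)) stop("quota must be positive")
  fs <- samplingRate(signal)
  nper <- as.integer(round(epochSeconds * fs))
  step <- max(1L, as.integer(round(nper * (1 - overlapFraction))))
  N <- nTimepoints(signal)
  if (N < nper) {
    warning("signal shorter than one epoch; returning no epochs")
    return(list())
  }
  starts <- seq.int(1L, N - nper + 1L, by = step)
  if (is.finite(quota)) starts <- utils::head(starts, quota)
  x <- samples(signal)
  lapply(starts, function(s) {
    multichannelSignal(x[, s:(s + nper - 1L), drop = FALSE], fs,
                       channelNames(signal))
  })
}

normalizeChannelLabel <- function(x) {
  x <- toupper(trimws(x))
  x <- sub("^EEG[ _]+", "", x)
  sub("-(REF|LE|AVG|AR|A)$", "", x)
}

#' Select and order channels by label
#'
#' Picks the requested channels out of a recording, in the requested
#' order. Matching is case-insensitive and tolerant of montage
#' decorations (an `EEG` prefix or a reference suffix such as `-REF` or
#' `-LE`), so `"fp1"` resolves `"EEG FP1-REF"`.
#'
#' @param recording a [MultichannelSignal-class] with channel labels.
#' @param labels character vector of requested labels.
#' @return a [MultichannelSignal-class] with `length(labels)` channels.
#' @export
selectChannels <- function(recording, labels) {
  stopifnot(is(recording, "MultichannelSignal"))
  have <- normalizeChannelLabel(channelNames(recording))
  want <- normalizeChannelLabel(labels)
  idx <- match(want, have)
  if (anyNA(idx))
    stop("channel label(s) not found in recording: ",
         paste(labels[is.na(idx)], collapse = ", "))
  multichannelSignal(samples(recording)[idx, , drop = FALSE],
                     samplingRate(recording), labels)
}
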