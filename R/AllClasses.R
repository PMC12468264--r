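#' @import methods
NULL

#' Multichannel time-domain signal
#'
#' Container for a C-channel, N-sample real signal with its sampling rate.
#' This is the unit every filtering, epoching and decomposition step
#' operates on. Channels are rows, time points are columns.
#'
#' @slot samples numeric matrix, C channels x N time points (arbitrary
#'   units).
#' @slot fs sampling rate in Hz.
#' @slot channelNames character vector of length C (possibly empty names).
#' @export
setClass("MultichannelSignal",
  representation(samples = "matrix", fs = "numeric",
                 channelNames = "character"))

setValidity("MultichannelSignal", function(object) {
  msgs <- character()
  if (!is.numeric(object@samples))
    msgs <- c(msgs, "samples must be a numeric matrix")
  if (any(!is.finite(object@samples)))
    msgs <- c(msgs, "samples contain non-finite values")
  if (nrow(object@samples) < 1L)
    msgs <- c(msgs, "at least one channel required")
  if (ncol(object@samples) < 4L)
    msgs <- c(msgs, "at least 4 time points required")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msgs <- c(msgs, "fs must be a single positive number")
  if (length(object@channelNames) != nrow(object@samples))
    msgs <- c(msgs, "channelNames length must equal channel count")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MultichannelSignal
#'
#' @param samples numeric matrix (channels x time) or a numeric vector
#'   (treated as one channel).
#' @param fs sampling rate in Hz.
#' @param channelNames optional channel labels.
#' @return a [MultichannelSignal-class] object.
#' @examples
#' sig <- multichannelSignal(rbind(sin(1:100 / 5), cos(1:100 / 5)), fs = 100)
#' nChannels(sig)
#' @export
multichannelSignal <- function(samples, fs, channelNames = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  storage.mode(samples) <- "double"
  if (is.null(channelNames)) {
    channelNames <- rownames(samples)
    if (is.null(channelNames))
      channelNames <- paste0("ch", seq_len(nrow(samples)))
  }
  new("MultichannelSignal", samples = samples, fs = as.numeric(fs),
      channelNames = as.character(channelNames))
}

#' Set of intrinsic mode functions from a joint decomposition
#'
#' Result of [mvmdDecompose()]: K intrinsic mode functions (IMFs) for each
#' of the C input channels, with one shared center frequency per mode
#' index. Center frequencies are reported in ascending order and the mode
#' axis is ordered to match.
#'
#' @slot modes numeric array K x C x N (same units as the input signal).
#' @slot centerFreqs K center frequencies in Hz, ascending.
#' @slot fs sampling rate of the decomposed signal in Hz.
#' @slot nIter number of ADMM iterations executed.
#' @slot converged whether the relative-change stopping rule was met.
#' @slot finalResidual last value of the relative-change statistic.
#' @slot history per-iteration values of the relative-change statistic.
#' @export
setClass("ModeSet",
  representation(modes = "array", centerFreqs = "numeric", fs = "numeric",
                 nIter = "integer", converged = "logical",
                 finalResidual = "numeric", history = "numeric"))

setValidity("ModeSet", function(object) {
  msgs <- character()
  d <- dim(object@modes)
  if (length(d) != 3L)
    msgs <- c(msgs, "modes must be a K x C x N array")
  if (any(!is.finite(object@modes)))
    msgs <- c(msgs, "modes contain non-finite values")
  if (length(object@centerFreqs) != d[1L])
    msgs <- c(msgs, "one center frequency per mode required")
  nyq <- object@fs / 2
  if (any(object@centerFreqs < 0 | object@centerFreqs > nyq))
    msgs <- c(msgs, "center frequencies must lie in [0, fs/2]")
  if (is.unsorted(object@centerFreqs))
    msgs <- c(msgs, "center frequencies must be ascending")
  if (length(msgs)) msgs else TRUE
})

#' Stacked spectrogram tensor for one epoch
#'
#' Classifier input: one short-time Fourier magnitude spectrogram per
#' (channel, mode) pair, stacked channel-major (all K modes of channel 1,
#' then channel 2, ...) into a (K*C) x F x T nonnegative array.
#'
#' @slot values nonnegative array (K*C) x F x T of spectrogram magnitudes.
#' @slot freqs F frequency-bin centers in Hz.
#' @slot times T frame centers in seconds.
#' @export
setClass("FeatureTensor",
  representation(values = "array", freqs = "numeric", times = "numeric"))

setValidity("FeatureTensor", function(object) {
  msgs <- character()
  d <- dim(object@values)
  if (length(d) != 3L)
    msgs <- c(msgs, "values must be a (K*C) x F x T array")
  if (any(!is.finite(object@values)) || any(object@values < 0))
    msgs <- c(msgs, "values must be finite nonnegative magnitudes")
  if (length(object@freqs) != d[2L])
    msgs <- c(msgs, "freqs length must equal the frequency axis")
  if (length(object@times) != d[3L])
    msgs <- c(msgs, "times length must equal the time axis")
  if (length(msgs)) msgs else TRUE
})

#' Evaluation report for one classification run
#'
#' Accuracy, sensitivity and specificity in percent, class-weighted F1 in
#' [0, 1], and the confusion matrix in raw counts and row-normalized form
#' (rows are true classes). For multi-class tasks sensitivity/specificity
#' are `NA` and per-class recalls carry the class-wise detail.
#'
#' @slot acc overall accuracy, percent.
#' @slot sen sensitivity (recall of the positive class), percent; `NA`
#'   for multi-class tasks.
#' @slot spe specificity (recall of the negative class), percent; `NA`
#'   for multi-class tasks.
#' @slot weightedF1 class-frequency-weighted mean of per-class F1 scores.
#' @slot confusion integer confusion matrix, rows = true classes.
#' @slot confusionNorm row-normalized confusion matrix (rows sum to 1).
#' @slot perClassRecall named per-class recalls in [0, 1].
#' @export
setClass("EvalReport",
  representation(acc = "numeric", sen = "numeric", spe = "numeric",
                 weightedF1 = "numeric", confusion = "matrix",
                 confusionNorm = "matrix", perClassRecall = "numeric"))

setValidity("EvalReport", function(object) {
  msgs <- character()
  if (object@acc < 0 || object@acc > 100)
    msgs <- c(msgs, "acc must be a percentage in [0, 100]")
  for (nm in c("sen", "spe")) {
    v <- slot(object, nm)
    if (!is.na(v) && (v < 0 || v > 100))
      msgs <- c(msgs, paste(nm, "must be a percentage in [0, 100]"))
  }
  if (object@weightedF1 < 0 || object@weightedF1 > 1)
    msgs <- c(msgs, "weightedF1 must lie in [0, 1]")
  rs <- rowSums(object@confusionNorm)
  nonzero <- rowSums(object@confusion) > 0
  if (any(abs(rs[nonzero] - 1) > 1e-9))
    msgs <- c(msgs, "normalized confusion rows must sum to 1")
  if (length(msgs)) msgs else TRUE
})
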