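#' STFT configuration
#'
#' Short-time Fourier transform settings for the per-mode spectrograms.
#' The defaults follow the study configuration: Hann window, hop of
#' `nperseg - overlap`, transform length `nfft` equal to the sampling
#' rate (1 Hz bin spacing), zero boundary padding by `nperseg/2` on each
#' side, and an inclusive 0--50 Hz crop of the frequency axis. For a
#' one-second epoch this yields 51 frequency points and 9 time frames at
#' both 512 Hz (nperseg 128, overlap 64) and 256 Hz (nperseg 64,
#' overlap 32).
#'
#' @param nperseg window length in samples.
#' @param overlap samples shared between consecutive windows
#'   (`overlap < nperseg`).
#' @param nfft transform length (`>= nperseg`); `NULL` means "use the
#'   sampling rate", giving 1 Hz bins.
#' @param bandKeep length-2 numeric, inclusive frequency band to retain
#'   in Hz.
#' @param boundaryPad zero-pad the series by `nperseg/2` at both ends so
#'   frames are centered on the epoch (T = N/hop + 1 frames for a
#'   divisible epoch).
#' @param window window type; only `"hann"` is provided.
#' @return a list of class `"STFTConfig"`.
#' @export
stftConfig <- function(nperseg = 128L, overlap = 64L, nfft = NULL,
                       bandKeep = c(0, 50), boundaryPad = TRUE,
                       window = "hann") {
  stopifnot(nperseg >= 2, overlap >= 0, length(bandKeep) == 2L,
            bandKeep[1L] < bandKeep[2L])
  if (overlap >= nperseg) stop("overlap must be smaller than nperseg")
  if (!is.null(nfft) && nfft < nperseg)
    stop("nfft must be at least nperseg")
  if (!identical(window, "hann")) stop("only the Hann window is supported")
  structure(list(nperseg = as.integer(nperseg), overlap = as.integer(overlap),
                 nfft = if (is.null(nfft)) NULL else as.integer(nfft),
                 bandKeep = as.numeric(bandKeep),
                 boundaryPad = isTRUE(boundaryPad), window = window),
            class = "STFTConfig")
}

hannWindow <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

#' Short-time Fourier magnitude spectrogram of one series
#'
#' Hann-windowed sliding DFT: frames advance by `nperseg - overlap`
#' samples, each frame is zero-padded to `nfft` and transformed, and the
#' magnitude (not power) of the nonnegative-frequency bins is returned.
#' With `boundaryPad` the series is zero-padded by `nperseg/2` at both
#' ends, so a one-second epoch divisible by the hop yields
#' `N/hop + 1` frames.
#'
#' @param x numeric vector, the mode (or signal) series.
#' @param cfg an [stftConfig()]. The band crop is NOT applied here; see
#'   [cropBand()] / [buildFeatureTensor()].
#' @param fs sampling rate in Hz (also the default transform length).
#' @return F x T nonnegative matrix with attributes `freqs` (Hz) and
#'   `times` (s, frame centers).
#' @export
stftMagnitude <- function(x, cfg, fs) {
  stopifnot(inherits(cfg, "STFTConfig"), length(x) >= 1, fs > 0)
  nperseg <- cfg$nperseg
  hop <- nperseg - cfg$overlap
  nfft <- if (is.null(cfg$nfft)) as.integer(round(fs)) else cfg$nfft
  if (nfft < nperseg) stop("nfft must be at least nperseg")
  pad <- if (cfg$boundaryPad) nperseg %/% 2L else 0L
  xp <- c(rep(0, pad), as.numeric(x), rep(0, pad))
  if (length(xp) < nperseg)
    xp <- c(xp, rep(0, nperseg - length(xp)))
  nFrames <- (length(xp) - nperseg) %/% hop + 1L
  starts <- (seq_len(nFrames) - 1L) * hop
  w <- hannWindow(nperseg)
  frames <- vapply(starts, function(s) xp[(s + 1L):(s + nperseg)] * w,
                   numeric(nperseg))
  frames <- rbind(frames, matrix(0, nfft - nperseg, nFrames))
  spec <- stats::mvfft(frames)
  Fbins <- nfft %/% 2L + 1L
  mag <- Mod(spec[seq_len(Fbins), , drop = FALSE])
  attr(mag, "freqs") <- (seq_len(Fbins) - 1) * fs / nfft
  attr(mag, "times") <- starts / fs
  mag
}

#' Crop a spectrogram to a frequency band
#'
#' Retains the rows whose bin frequencies satisfy `low <= f <= high`
#' (inclusive at both ends). With 1 Hz bin spacing, keeping 0--50 Hz
#' retains 51 bins.
#'
#' @param spec F x T spectrogram matrix.
#' @param freqs frequency of each row in Hz.
#' @param low,high band edges in Hz, `low < high`.
#' @return the cropped matrix with a `freqs` attribute for the retained
#'   bins (any `times` attribute is preserved).
#' @export
cropBand <- function(spec, freqs, low, high) {
  stopifnot(low < high, nrow(spec) == length(freqs))
  keep <- which(freqs >= low & freqs <= high)
  if (!length(keep)) stop("no frequency bins inside the requested band")
  out <- spec[keep, , drop = FALSE]
  attr(out, "freqs") <- freqs[keep]
  attr(out, "times") <- attr(spec, "times")
  out
}

#' Assemble the classifier input tensor from a ModeSet
#'
#' Computes one band-cropped STFT magnitude spectrogram per
#' (channel, mode) pair and stacks them channel-major (all K modes of
#' channel 1 first) into a (K*C) x F x T [FeatureTensor-class]. Under the
#' study configurations this reproduces the (8, 51, 9) and (56, 51, 9)
#' input shapes of the two classification tasks.
#'
#' @param modeSet a [ModeSet-class].
#' @param cfg an [stftConfig()].
#' @return a [FeatureTensor-class].
#' @export
buildFeatureTensor <- function(modeSet, cfg) {
  stopifnot(is(modeSet, "ModeSet"), inherits(cfg, "STFTConfig"))
  K <- nModes(modeSet); C <- nChannels(modeSet)
  fs <- samplingRate(modeSet)
  first <- NULL
  vals <- NULL
  for (cc in seq_len(C)) {
    for (k in seq_len(K)) {
      spec <- stftMagnitude(modeSet@modes[k, cc, ], cfg, fs)
      spec <- cropBand(spec, attr(spec, "freqs"),
                       cfg$bandKeep[1L], cfg$bandKeep[2L])
      if (is.null(first)) {
        first <- spec
        vals <- array(0, c(K * C, nrow(spec), ncol(spec)))
      }
      vals[(cc - 1L) * K + k, , ] <- spec
    }
  }
  new("FeatureTensor", values = vals, freqs = attr(first, "freqs"),
      times = attr(first, "times"))
}

#' Decompose an epoch and build its feature tensor
#'
#' Convenience wrapper: [mvmdDecompose()] followed by
#' [buildFeatureTensor()].
#'
#' @param signal a [MultichannelSignal-class] epoch.
#' @param mvmdCfg an [mvmdConfig()].
#' @param stftCfg an [stftConfig()].
#' @return a [FeatureTensor-class].
#' @export
epochFeatures <- function(signal, mvmdCfg, stftCfg) {
  buildFeatureTensor(mvmdDecompose(signal, mvmdCfg), stftCfg)
}
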