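#' @describeIn MultichannelSignal-class channel x time sample matrix.
#' @param object a package object.
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @export
setMethod("samples", "MultichannelSignal", function(object) object@samples)

#' @describeIn MultichannelSignal-class sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @export
setMethod("samplingRate", "MultichannelSignal", function(object) object@fs)

#' @export
setMethod("samplingRate", "ModeSet", function(object) object@fs)

#' @describeIn MultichannelSignal-class number of channels C.
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @export
setMethod("nChannels", "MultichannelSignal",
          function(object) nrow(object@samples))

#' @export
setMethod("nChannels", "ModeSet", function(object) dim(object@modes)[2L])

#' @describeIn MultichannelSignal-class number of time points N.
#' @export
setGeneric("nTimepoints", function(object) standardGeneric("nTimepoints"))

#' @export
setMethod("nTimepoints", "MultichannelSignal",
          function(object) ncol(object@samples))

#' @export
setMethod("nTimepoints", "ModeSet", function(object) dim(object@modes)[3L])

#' @describeIn MultichannelSignal-class channel labels.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @export
setMethod("channelNames", "MultichannelSignal",
          function(object) object@channelNames)

#' @describeIn ModeSet-class K x C x N array of intrinsic mode functions.
#' @param object a package object.
#' @export
setGeneric("modeArray", function(object) standardGeneric("modeArray"))

#' @export
setMethod("modeArray", "ModeSet", function(object) object@modes)

#' @describeIn ModeSet-class shared center frequencies in Hz, ascending.
#' @export
setGeneric("centerFreqs", function(object) standardGeneric("centerFreqs"))

#' @export
setMethod("centerFreqs", "ModeSet", function(object) object@centerFreqs)

#' @describeIn ModeSet-class number of extracted modes K.
#' @export
setGeneric("nModes", function(object) standardGeneric("nModes"))

#' @export
setMethod("nModes", "ModeSet", function(object) dim(object@modes)[1L])

#' @describeIn FeatureTensor-class (K*C) x F x T magnitude array.
#' @param object a package object.
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' @export
setMethod("featureValues", "FeatureTensor", function(object) object@values)

#' @describeIn EvalReport-class named list of the scalar metrics.
#' @param object a package object.
#' @export
setGeneric("metrics", function(object) standardGeneric("metrics"))

#' @export
setMethod("metrics", "EvalReport", function(object) {
  list(acc = object@acc, sen = object@sen, spe = object@spe,
       weightedF1 = object@weightedF1)
})

#' @describeIn EvalReport-class confusion matrix; `normalized = TRUE`
#'   returns the row-normalized form.
#' @param normalized return row-normalized proportions instead of counts.
#' @export
setGeneric("confusionMatrix",
           function(object, normalized = FALSE)
             standardGeneric("confusionMatrix"))

#' @export
setMethod("confusionMatrix", "EvalReport", function(object, normalized = FALSE) {
  if (normalized) object@confusionNorm else object@confusion
})

setMethod("show", "MultichannelSignal", function(object) {
  cat(sprintf("MultichannelSignal: %d channel(s) x %d samples @ %g Hz (%.3g s)\n",
              nChannels(object), nTimepoints(object), object@fs,
              nTimepoints(object) / object@fs))
  cat(" channels:", paste(utils::head(object@channelNames, 8L),
                          collapse = ", "),
      if (nChannels(object) > 8L) "..." else "", "\n")
})

setMethod("show", "ModeSet", function(object) {
  cat(sprintf("ModeSet: K=%d modes x %d channel(s) x %d samples @ %g Hz\n",
              nModes(object), nChannels(object), nTimepoints(object),
              object@fs))
  cat(sprintf(" center frequencies (Hz): %s\n",
              paste(signif(object@centerFreqs, 4), collapse = ", ")))
  cat(sprintf(" %s after %d iterations (final relative change %.3g)\n",
              if (object@converged) "converged" else "NOT converged",
              object@nIter, object@finalResidual))
})

setMethod("show", "FeatureTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("FeatureTensor: (%d, %d, %d) [(K*C) x freq x time]\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf(" freq %g-%g Hz (%d bins), time %g-%g s (%d frames)\n",
              min(object@freqs), max(object@freqs), d[2L],
              min(object@times), max(object@times), d[3L]))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  cat(sprintf(" ACC %.2f%%", object@acc))
  if (!is.na(object@sen)) cat(sprintf("  SEN %.2f%%", object@sen))
  if (!is.na(object@spe)) cat(sprintf("  SPE %.2f%%", object@spe))
  cat(sprintf("  weighted F1 %.3f\n", object@weightedF1))
  cat(" confusion (rows = true):\n")
  print(object@confusion)
})
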