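#' @rdname SpectralEstimate-class
#' @param x An object.
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))

#' @rdname SpectralEstimate-class
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname SpectralEstimate-class
#' @param freq Frequency in Hz (must align with a spectral bin).
#' @export
setGeneric("binAt", function(x, freq) standardGeneric("binAt"))

#' @rdname RecordingSet-class
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname RecordingSet-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname RecordingSet-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname RecordingSet-class
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname RecordingSet-class
#' @param i Trial index.
#' @export
setGeneric("trialMatrix", function(x, i) standardGeneric("trialMatrix"))

#' @rdname RecordingSet-class
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))

#' @rdname GainControlParams-class
#' @export
setGeneric("suppressionWeight", function(x) standardGeneric("suppressionWeight"))

#' @rdname GainControlParams-class
#' @export
setGeneric("saturationConstant", function(x) standardGeneric("saturationConstant"))

#' @rdname GainControlParams-class
#' @export
setGeneric("noiseParam", function(x) standardGeneric("noiseParam"))

#' @rdname GainControlParams-class
#' @export
setGeneric("responseScale", function(x) standardGeneric("responseScale"))

#' @rdname GainControlParams-class
#' @export
setGeneric("matchingMode", function(x) standardGeneric("matchingMode"))

#' @rdname PosteriorFit-class
#' @export
setGeneric("posteriorDraws", function(x) standardGeneric("posteriorDraws"))

#' @rdname PosteriorFit-class
#' @export
setGeneric("posteriorSummary", function(x) standardGeneric("posteriorSummary"))

#' @rdname PosteriorFit-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname StimCondition-class
#' @export
setGeneric("ocularConfig", function(x) standardGeneric("ocularConfig"))

#' @rdname StimCondition-class
#' @param params A \linkS4class{GainControlParams} object.
#' @param freq Analysis frequency in Hz.
#' @export
setGeneric("predictedAmplitude", function(x, params, freq)
  standardGeneric("predictedAmplitude"))
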