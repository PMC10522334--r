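## Central S4 classes.  Validity methods enforce the contracts the rest of
## the package relies on; user code should go through the constructor
## functions and accessors, never @ slots.

#' Gain-control model parameters
#'
#' Parameter set for the binocular contrast gain-control model.  Each
#' monocular channel responds with \eqn{C_{own}^2 / (Z + C_{own} + w
#' C_{other})}, where \eqn{Z} is a saturation constant (in contrast units,
#' \%) that shifts the contrast-response function laterally and \eqn{w}
#' weights suppression from the other eye.  The two channel responses are
#' summed and scaled: \eqn{R_{max}(Resp_L + Resp_R) + n}.  The numerator
#' exponent is fixed at 2 (it trades off with \eqn{w} if left free).
#'
#' In \emph{matching mode} (\code{Rmax = NA}) the output scaling is absent
#' and \code{n} is interpreted as the decision-noise standard deviation of
#' the matching observer rather than an additive response offset.
#'
#' @slot Z numeric, saturation constant (> 0), percent contrast units.
#' @slot w numeric, interocular suppression weight (>= 0).
#' @slot n numeric, noise parameter (>= 0); response units, or
#'   decision-noise SD in matching mode.
#' @slot Rmax numeric, output scaling (> 0), or \code{NA} for matching mode.
#' @slot p numeric, numerator exponent, always 2.
#'
#' @param Z,w,n,Rmax See slots.
#' @param x A \code{GainControlParams} object.
#' @return \code{gainParams()} returns a validated
#'   \code{GainControlParams} object.
#' @examples
#' gainParams(Z = 3.44, w = 0.61, n = 0.01, Rmax = 0.00023)
#' gainParams(Z = 0.30, w = 0.09, n = 5.10)  # matching mode
#' @aliases suppressionWeight saturationConstant noiseParam responseScale
#'   matchingMode
#' @name GainControlParams-class
#' @exportClass GainControlParams
setClass("GainControlParams",
  representation(Z = "numeric", w = "numeric", n = "numeric",
                 Rmax = "numeric", p = "numeric"),
  prototype(p = 2))

setValidity("GainControlParams", function(object) {
  msg <- character()
  for (s in c("Z", "w", "n", "Rmax", "p"))
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, sprintf("slot '%s' must have length 1", s))
  if (length(msg)) return(msg)
  if (!is.finite(object@Z) || object@Z <= 0) msg <- c(msg, "Z must be > 0")
  if (!is.finite(object@w) || object@w < 0) msg <- c(msg, "w must be >= 0")
  if (!is.finite(object@n) || object@n < 0) msg <- c(msg, "n must be >= 0")
  if (!is.na(object@Rmax) && (!is.finite(object@Rmax) || object@Rmax <= 0))
    msg <- c(msg, "Rmax must be > 0 when present")
  if (object@p != 2) msg <- c(msg, "numerator exponent p is fixed at 2")
  if (length(msg)) msg else TRUE
})

#' @rdname GainControlParams-class
#' @export
gainParams <- function(Z, w, n, Rmax = NA_real_) {
  new("GainControlParams", Z = as.numeric(Z), w = as.numeric(w),
      n = as.numeric(n), Rmax = as.numeric(Rmax), p = 2)
}

setMethod("suppressionWeight", "GainControlParams", function(x) x@w)
setMethod("saturationConstant", "GainControlParams", function(x) x@Z)
setMethod("noiseParam", "GainControlParams", function(x) x@n)
setMethod("responseScale", "GainControlParams", function(x) x@Rmax)
setMethod("matchingMode", "GainControlParams", function(x) is.na(x@Rmax))

setMethod("show", "GainControlParams", function(object) {
  cat("GainControlParams (binocular contrast gain control)\n")
  cat(sprintf("  Z = %g, w = %g, n = %g, Rmax = %s, exponent = 2\n",
              object@Z, object@w, object@n,
              if (is.na(object@Rmax)) "<matching mode>" else
                format(object@Rmax)))
})

.OCULAR_CONFIGS <- c("monocular", "binocular", "dichoptic",
                     "monocular_cross", "binocular_cross", "dichoptic_cross")

#' Stimulus condition
#'
#' One ocular configuration of the flicker experiment: which eye(s) see the
#' target flicker, at what Michelson temporal contrast and frequency, and
#' whether the other eye sees a mask (fixed 48\% contrast for dichoptic
#' configurations; 1.6 Hz for the cross-frequency configurations).
#'
#' @slot ocularConfig one of \code{"monocular"}, \code{"binocular"},
#'   \code{"dichoptic"}, \code{"monocular_cross"}, \code{"binocular_cross"},
#'   \code{"dichoptic_cross"}.
#' @slot targetContrast percent Michelson temporal contrast in [0, 100].
#' @slot maskContrast percent; 48 for dichoptic configurations, else 0 or
#'   the target contrast (binocular cross).
#' @slot targetFreq Hz (2 in the standard design).
#' @slot maskFreq Hz (1.6 for cross-frequency configurations, else \code{NA}).
#' @slot targetEye \code{"left"} or \code{"right"}.
#'
#' @param config,targetContrast,maskContrast,targetFreq,maskFreq,targetEye
#'   See slots.  \code{maskContrast} and \code{maskFreq} default to the
#'   values the configuration dictates.
#' @param x A \code{StimCondition}.
#' @name StimCondition-class
#' @aliases ocularConfig predictedAmplitude
#' @exportClass StimCondition
setClass("StimCondition",
  representation(ocularConfig = "character", targetContrast = "numeric",
                 maskContrast = "numeric", targetFreq = "numeric",
                 maskFreq = "numeric", targetEye = "character"))

setValidity("StimCondition", function(object) {
  msg <- character()
  if (!object@ocularConfig %in% .OCULAR_CONFIGS)
    msg <- c(msg, sprintf("unknown ocular configuration '%s'",
                          object@ocularConfig))
  if (object@targetContrast < 0 || object@targetContrast > 100)
    msg <- c(msg, "targetContrast must lie in [0, 100]")
  if (object@maskContrast < 0 || object@maskContrast > 100)
    msg <- c(msg, "maskContrast must lie in [0, 100]")
  cross <- grepl("_cross$", object@ocularConfig)
  if (cross && is.na(object@maskFreq))
    msg <- c(msg, "cross-frequency configurations need a mask frequency")
  if (!cross && !is.na(object@maskFreq))
    msg <- c(msg, "maskFreq only applies to cross-frequency configurations")
  if (grepl("^dichoptic", object@ocularConfig) && object@maskContrast != 48)
    msg <- c(msg, "dichoptic configurations have a fixed 48% mask contrast")
  if (!object@targetEye %in% c("left", "right"))
    msg <- c(msg, "targetEye must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' @rdname StimCondition-class
#' @export
stimCondition <- function(config, targetContrast, maskContrast = NULL,
                          targetFreq = 2, maskFreq = NULL,
                          targetEye = "left") {
  cross <- grepl("_cross$", config)
  if (is.null(maskFreq)) maskFreq <- if (cross) 1.6 else NA_real_
  if (is.null(maskContrast)) {
    maskContrast <- switch(config,
      monocular = 0, monocular_cross = 0,
      binocular = targetContrast, binocular_cross = targetContrast,
      dichoptic = 48, dichoptic_cross = 48,
      stop("unknown ocular configuration '", config, "'"))
  }
  new("StimCondition", ocularConfig = config,
      targetContrast = as.numeric(targetContrast),
      maskContrast = as.numeric(maskContrast),
      targetFreq = as.numeric(targetFreq), maskFreq = as.numeric(maskFreq),
      targetEye = targetEye)
}

setMethod("ocularConfig", "StimCondition", function(x) x@ocularConfig)

setMethod("show", "StimCondition", function(object) {
  cat(sprintf("StimCondition: %s, target %g%% @ %g Hz",
              object@ocularConfig, object@targetContrast, object@targetFreq))
  if (object@maskContrast > 0 &&
      !object@ocularConfig %in% c("binocular"))
    cat(sprintf(", mask %g%%%s", object@maskContrast,
                if (!is.na(object@maskFreq))
                  sprintf(" @ %g Hz", object@maskFreq) else ""))
  cat("\n")
})

#' Set of recorded (or simulated) trials for one modality
#'
#' Container for trial-level time series: pupil diameter traces (120
#' samples/s, mm, up to two eye channels) or EEG voltage traces (1000
#' samples/s, microvolts, electrode channels from a 64-electrode montage).
#' Each trial is a channels-by-samples matrix; all trials share the
#' sampling rate and length.  Missing samples (dropped frames) are stored
#' as \code{NA} and must be resolved by \code{\link{interpolateGaps}}
#' before spectral analysis.
#'
#' @slot modality \code{"pupil"} or \code{"eeg"}.
#' @slot rate sampling rate, samples/s.
#' @slot channels channel names (eye labels or electrode names).
#' @slot trials list of numeric matrices, channels x samples.
#' @slot info data.frame with one row per trial (participant, condition,
#'   trial, and any design columns).
#'
#' @param modality,rate,channels,trials,info See slots.
#' @param x A \code{RecordingSet}.
#' @param i Trial index.
#' @name RecordingSet-class
#' @aliases modality samplingRate channelNames nTrials trialMatrix trialInfo
#' @exportClass RecordingSet
setClass("RecordingSet",
  representation(modality = "character", rate = "numeric",
                 channels = "character", trials = "list",
                 info = "data.frame"))

setValidity("RecordingSet", function(object) {
  msg <- character()
  if (!object@modality %in% c("pupil", "eeg"))
    msg <- c(msg, "modality must be 'pupil' or 'eeg'")
  if (object@rate <= 0) msg <- c(msg, "rate must be positive")
  if (object@modality == "pupil" && length(object@channels) > 2)
    msg <- c(msg, "pupil recordings have at most two channels")
  if (object@modality == "eeg" &&
      !all(object@channels %in% eegMontage64()))
    msg <- c(msg, "eeg channel names must come from the 64-electrode montage")
  if (length(object@trials)) {
    dims <- vapply(object@trials, dim, integer(2))
    if (any(dims[1, ] != length(object@channels)))
      msg <- c(msg, "every trial must have one row per channel")
    if (length(unique(dims[2, ])) > 1)
      msg <- c(msg, "all trials must have the same number of samples")
  }
  if (nrow(object@info) != length(object@trials))
    msg <- c(msg, "info must have one row per trial")
  if (length(msg)) msg else TRUE
})

#' @rdname RecordingSet-class
#' @export
recordingSet <- function(modality, rate, channels, trials, info) {
  trials <- lapply(trials, function(tr) {
    if (is.null(dim(tr))) tr <- matrix(tr, nrow = 1)
    tr
  })
  new("RecordingSet", modality = modality, rate = as.numeric(rate),
      channels = as.character(channels), trials = trials,
      info = as.data.frame(info))
}

setMethod("modality", "RecordingSet", function(x) x@modality)
setMethod("samplingRate", "RecordingSet", function(x) x@rate)
setMethod("channelNames", "RecordingSet", function(x) x@channels)
setMethod("nTrials", "RecordingSet", function(x) length(x@trials))
setMethod("trialMatrix", "RecordingSet", function(x, i) {
  tr <- x@trials[[i]]
  rownames(tr) <- x@channels
  tr
})
setMethod("trialInfo", "RecordingSet", function(x) x@info)

setMethod("show", "RecordingSet", function(object) {
  ns <- if (length(object@trials)) ncol(object@trials[[1]]) else 0L
  cat(sprintf("RecordingSet: %s, %d trial(s), %d channel(s), %g Hz, %g s\n",
              object@modality, length(object@trials),
              length(object@channels), object@rate, ns / object@rate))
})

#' Complex amplitude spectrum of one epoch
#'
#' Fourier amplitude spectrum with the sine-amplitude scaling convention:
#' a pure sinusoid \eqn{A \sin(2\pi f t + \phi)} with an integer number of
#' cycles in the window yields \code{Mod(binAt(x, f)) == A}.  Bin spacing
#' is \code{1/duration} Hz (0.1 Hz for the standard 10-s epochs).
#'
#' @slot amp complex amplitudes, one per frequency bin (DC first).
#' @slot freq bin frequencies in Hz.
#' @slot rate sampling rate of the source epoch.
#' @slot duration epoch duration in seconds.
#'
#' @param x A \code{SpectralEstimate}.
#' @param freq Frequency in Hz; must align with a bin to within 1e-6 Hz.
#' @name SpectralEstimate-class
#' @aliases amplitudes frequencies binAt
#' @exportClass SpectralEstimate
setClass("SpectralEstimate",
  representation(amp = "complex", freq = "numeric", rate = "numeric",
                 duration = "numeric"))

setValidity("SpectralEstimate", function(object) {
  msg <- character()
  if (length(object@amp) != length(object@freq))
    msg <- c(msg, "amp and freq must have equal length")
  if (length(object@freq) > 1) {
    res <- object@freq[2] - object@freq[1]
    if (abs(res - 1 / object@duration) > 1e-9)
      msg <- c(msg, "bin resolution must equal 1/duration")
  }
  if (length(msg)) msg else TRUE
})

setMethod("amplitudes", "SpectralEstimate", function(x) x@amp)
setMethod("frequencies", "SpectralEstimate", function(x) x@freq)
setMethod("binAt", "SpectralEstimate", function(x, freq) {
  i <- which(abs(x@freq - freq) < 1e-6)
  if (length(i) != 1L)
    stop("frequency ", freq, " Hz does not align with a spectral bin")
  x@amp[i]
})

setMethod("show", "SpectralEstimate", function(object) {
  cat(sprintf("SpectralEstimate: %d bins, %.3g Hz resolution, 0-%g Hz\n",
              length(object@amp), 1 / object@duration, max(object@freq)))
})

#' Posterior fit of the gain-control model
#'
#' MCMC posterior over the gain-control parameters, with medians, central
#' 95\% intervals and convergence diagnostics (split R-hat, effective
#' sample size).  The reported point estimate is the posterior median.
#' A fit with any R-hat >= 1.05 is flagged as non-converged (the result is
#' still returned, but marked).
#'
#' @slot draws data.frame with columns \code{chain}, \code{draw} and one
#'   column per parameter.
#' @slot summary data.frame: parameter, median, lower95, upper95, rhat, ess.
#' @slot kind dataset kind: \code{"pupil"}, \code{"eeg_1f"},
#'   \code{"eeg_2f"} or \code{"matching"}.
#' @slot converged logical.
#' @slot config list of sampler settings actually used.
#'
#' @param x A \code{PosteriorFit}.
#' @name PosteriorFit-class
#' @aliases posteriorDraws posteriorSummary isConverged
#' @exportClass PosteriorFit
setClass("PosteriorFit",
  representation(draws = "data.frame", summary = "data.frame",
                 kind = "character", converged = "logical",
                 config = "list"))

setMethod("posteriorDraws", "PosteriorFit", function(x) x@draws)
setMethod("posteriorSummary", "PosteriorFit", function(x) x@summary)
setMethod("isConverged", "PosteriorFit", function(x) x@converged)

setMethod("show", "PosteriorFit", function(object) {
  cat(sprintf("PosteriorFit (%s data)%s\n", object@kind,
              if (object@converged) "" else "  ** NOT CONVERGED **"))
  print(object@summary, row.names = FALSE, digits = 4)
})
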