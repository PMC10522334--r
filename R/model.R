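## Binocular contrast gain-control model.
##
## Each eye's channel divides its squared contrast by a gain pool that
## contains its own contrast plus a weighted copy of the other eye's
## contrast (interocular suppression).  The channel outputs are summed,
## scaled and offset by a noise parameter.  The same equations run on
## scalar contrasts and, pointwise, on time-varying contrast waveforms.

#' Monocular channel response
#'
#' Response of one eye's channel under interocular suppression:
#' \deqn{Resp = \frac{C_{own}^2}{Z + C_{own} + w\,C_{other}}}{
#'   Resp = Cown^2 / (Z + Cown + w * Cother)}
#' The response is symmetric under eye relabeling, strictly increasing in
#' the channel's own contrast and (for \code{w > 0}) strictly decreasing
#' in the other eye's contrast.
#'
#' @param cOwn,cOther Percent Michelson temporal contrast (>= 0);
#'   vectorised.
#' @param params A \linkS4class{GainControlParams} object.
#' @return Numeric channel response in model units.
#' @examples
#' p <- gainParams(Z = 3.44, w = 0.61, n = 0.01, Rmax = 0.00023)
#' channelResponse(48, 48, p)  # 2304 / 80.72
#' @export
channelResponse <- function(cOwn, cOther, params) {
  stopifnot(is(params, "GainControlParams"))
  if (any(cOwn < 0) || any(cOther < 0))
    stop("contrast must be non-negative")
  cOwn^2 / (params@Z + cOwn + params@w * cOther)
}

#' Binocular response
#'
#' Sums the two monocular channel responses and applies output scaling and
#' the additive noise parameter: \eqn{R_{max}(Resp_L + Resp_R) + n}.  In
#' matching mode (no \code{Rmax}) the raw sum \eqn{Resp_L + Resp_R} is
#' returned: an additive constant cancels in any response difference, so
#' there \code{n} acts as the decision-noise SD instead (see
#' \code{\link{simulateMatchingBlock}}).
#'
#' @param cL,cR Percent contrast in the left and right eyes (vectorised).
#' @inheritParams channelResponse
#' @return Numeric binocular response.
#' @examples
#' p <- gainParams(Z = 2.62, w = 0.02, n = 0.15, Rmax = 0.00336)
#' binocularResponse(96, 96, p)
#' @export
binocularResponse <- function(cL, cR, params) {
  r <- channelResponse(cL, cR, params) + channelResponse(cR, cL, params)
  if (matchingMode(params)) r else params@Rmax * r + params@n
}

#' Binocular to monocular response ratio
#'
#' Ratio of the model's binocular response (equal contrast in both eyes)
#' to its monocular response at the same contrast.  Without noise the
#' ratio is \eqn{2(Z + c)/(Z + c(1 + w))}: exactly 2 when \code{w = 0},
#' approaching 1 from above as \code{w} grows toward 1 at high contrast.
#'
#' @param contrast Percent contrast (> 0).
#' @inheritParams channelResponse
#' @param includeNoise If \code{FALSE} (default) the ratio is computed on
#'   the noise-free scaled responses.
#' @return Numeric ratio.
#' @export
binocularRatio <- function(contrast, params, includeNoise = FALSE) {
  stopifnot(is(params, "GainControlParams"))
  if (any(contrast <= 0) && !includeNoise)
    stop("noise-free ratio undefined at zero contrast")
  if (includeNoise) {
    binocularResponse(contrast, contrast, params) /
      binocularResponse(contrast, 0, params)
  } else {
    ## noise-free: Rmax cancels, monocular sum collapses to one channel
    2 * channelResponse(contrast, contrast, params) /
      channelResponse(contrast, 0, params)
  }
}

#' Waveform-mode model response
#'
#' Runs the gain-control equations pointwise on time-varying contrast
#' inputs.  Each eye's signed instantaneous contrast is half-wave
#' rectified into an on-channel (negative lobes set to zero) before the
#' channel equations are applied at every time point; this static
#' nonlinearity is what generates odd harmonics alongside the even
#' harmonics of the squaring numerator, and (when \code{w > 0}) the
#' intermodulation terms at sums and differences of dichoptic input
#' frequencies.
#'
#' @param waveL,waveR Numeric vectors: instantaneous (signed) percent
#'   contrast in each eye, equal length.
#' @param rate Sampling rate, samples/s.
#' @inheritParams channelResponse
#' @return Numeric response waveform of the same length.
#' @examples
#' p <- gainParams(Z = 2.62, w = 0.02, n = 0.15, Rmax = 0.00336)
#' t <- seq(0, 10, by = 1 / 1000); t <- t[-length(t)]
#' y <- responseWaveform(96 * sin(2 * pi * 2 * t),
#'                       96 * sin(2 * pi * 2 * t), rate = 1000, params = p)
#' @export
responseWaveform <- function(waveL, waveR, rate, params) {
  stopifnot(is(params, "GainControlParams"))
  if (length(waveL) != length(waveR))
    stop("eye waveforms must have equal length")
  if (rate <= 0) stop("sampling rate must be positive")
  L <- pmax(waveL, 0)
  R <- pmax(waveR, 0)
  r <- L^2 / (params@Z + L + params@w * R) +
       R^2 / (params@Z + R + params@w * L)
  out <- if (matchingMode(params)) r else params@Rmax * r + params@n
  structure(out, rate = rate)
}

#' Model-predicted contrast-matching contour
#'
#' For each interocular ratio \eqn{r}, finds the target contrast \eqn{c}
#' at which a target with per-eye contrasts \eqn{(c, r c)} produces the
#' same binocular response as a binocular standard, by monotone root
#' finding (bisection; the response is strictly increasing in target
#' contrast, so the root is unique).  Points are mirrored for the
#' symmetric eye assignment.
#'
#' @inheritParams channelResponse
#' @param standardContrast Percent contrast of the binocular standard,
#'   in (0, 100].
#' @param ratios Interocular contrast ratios in [0, 1].
#' @param ceiling Contrast ceiling; matches are searched up to
#'   \code{10 * ceiling} before an unreachable-match error is raised.
#' @return data.frame with columns \code{ratio}, \code{side}
#'   (\code{"left"}/\code{"right"} dominant), \code{cL}, \code{cR}.
#' @examples
#' p <- gainParams(Z = 0.30, w = 0.09, n = 5.10)
#' modelMatchingContour(p, 48, ratios = c(0, 0.5, 1))
#' @export
modelMatchingContour <- function(params, standardContrast,
                                 ratios = c(0, 0.25, 0.5, 0.75, 1),
                                 ceiling = 100) {
  stopifnot(is(params, "GainControlParams"))
  if (standardContrast <= 0 || standardContrast > 100)
    stop("standardContrast must lie in (0, 100]")
  if (any(ratios < 0 | ratios > 1)) stop("ratios must lie in [0, 1]")
  target <- binocularResponse(standardContrast, standardContrast, params)
  solveOne <- function(r) {
    if (r == 1) return(standardContrast)
    f <- function(c) binocularResponse(c, r * c, params) - target
    hi <- 10 * ceiling
    if (f(hi) < 0)
      stop("unreachable match: no solution below 10x the contrast ceiling")
    lo <- 0
    while ((hi - lo) / max(hi, 1) > 1e-6) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  res <- lapply(ratios, function(r) {
    c0 <- solveOne(r)
    pts <- data.frame(ratio = r, side = c("left", "right"),
                      cL = c(c0, r * c0), cR = c(r * c0, c0),
                      stringsAsFactors = FALSE)
    if (r == 1) pts[1, , drop = FALSE] else pts
  })
  do.call(rbind, res)
}

#' Canonical matching contours
#'
#' Predictions of the two canonical summation rules for the dichoptic
#' matching task: linear combination (locus \eqn{c_L + c_R = 2 \cdot
#' standard}) and winner-take-all / MAX (locus \eqn{\max(c_L, c_R) =
#' standard}).
#'
#' @param rule \code{"linear"} or \code{"max"}.
#' @inheritParams modelMatchingContour
#' @return data.frame as for \code{\link{modelMatchingContour}}.
#' @export
canonicalContour <- function(rule = c("linear", "max"), standardContrast,
                             ratios = c(0, 0.25, 0.5, 0.75, 1)) {
  rule <- match.arg(rule)
  if (standardContrast <= 0 || standardContrast > 100)
    stop("standardContrast must lie in (0, 100]")
  res <- lapply(ratios, function(r) {
    c0 <- switch(rule,
                 linear = 2 * standardContrast / (1 + r),
                 max = standardContrast)
    pts <- data.frame(ratio = r, side = c("left", "right"),
                      cL = c(c0, r * c0), cR = c(r * c0, c0),
                      stringsAsFactors = FALSE)
    if (r == 1) pts[1, , drop = FALSE] else pts
  })
  do.call(rbind, res)
}

#' Scalar-mode amplitude prediction for a stimulus condition
#'
#' Maps a \linkS4class{StimCondition} to the model's predicted steady-state
#' amplitude at an analysis frequency.  Eyes flickering at the requested
#' frequency contribute their channel response (with suppression driven by
#' the other eye's total contrast); the sum is scaled by \code{Rmax} and
#' offset by \code{n}.  For same-frequency configurations at the target
#' frequency this reduces to \code{\link{binocularResponse}} of the
#' per-eye contrast pair.
#'
#' @param x A \linkS4class{StimCondition}.
#' @param params A \linkS4class{GainControlParams}.
#' @param freq Analysis frequency (defaults to the condition's target
#'   frequency).
#' @return Predicted scalar amplitude.
#' @rdname StimCondition-class
#' @export
setMethod("predictedAmplitude", "StimCondition",
  function(x, params, freq) {
    if (missing(freq)) freq <- x@targetFreq
    ## per-eye contrast at each frequency: target eye carries the target
    ## component, the other eye carries the mask component (same frequency
    ## for plain configs, maskFreq for cross configs)
    tc <- x@targetContrast; mc <- x@maskContrast
    maskFreq <- if (is.na(x@maskFreq)) x@targetFreq else x@maskFreq
    contribution <- 0
    if (isTRUE(all.equal(freq, x@targetFreq)))
      contribution <- contribution + channelResponse(tc, mc, params)
    if (mc > 0 && isTRUE(all.equal(freq, maskFreq)))
      contribution <- contribution + channelResponse(mc, tc, params)
    if (matchingMode(params)) contribution
    else params@Rmax * contribution + params@n
  })

#' Standard factorial condition design
#'
#' The six ocular configurations crossed with the five target contrast
#' levels (6, 12, 24, 48, 96\%), mask fixed at 48\% for dichoptic
#' configurations and 1.6 Hz for cross-frequency configurations.
#'
#' @param configs Ocular configurations to include.
#' @param contrasts Target contrast levels (percent).
#' @return data.frame with one row per condition cell and a
#'   \code{condition} label column.
#' @export
conditionDesign <- function(configs = .OCULAR_CONFIGS,
                            contrasts = c(6, 12, 24, 48, 96)) {
  d <- expand.grid(config = configs, contrast = contrasts,
                   stringsAsFactors = FALSE)
  d$condition <- paste0(d$config, "_", d$contrast)
  d[order(match(d$config, configs), d$contrast), , drop = FALSE]
}

#' 64-electrode montage names
#'
#' Electrode labels of the extended 10-10 system used by 64-channel EEG
#' caps (includes the four occipital electrodes POz, Oz, O1, O2 that the
#' analysis averages).
#'
#' @return Character vector of 64 electrode names.
#' @export
eegMontage64 <- function() {
  c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
    "O1", "Oz", "O2", "M1")
}
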