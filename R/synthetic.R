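## Synthetic-data generators.  Every input the analysis pipeline consumes
## can be generated here: trial-level complex amplitudes with the noise
## structure the statistics assume (isotropic complex Gaussian), raw trial
## time series for both modalities, and full simulated matching sessions.
## Each generator is a pure function of (config, seed).

## Expand a design cell into one row per stimulated frequency.
##
## When both eyes flicker at the same frequency their channel responses
## sum into a single spectral bin (role "both"); in the cross-frequency
## configurations each eye's channel is resolved at its own frequency
## (roles "target" and "mask", suppression still crossing between eyes).
.conditionRows <- function(config, contrast) {
  tc <- contrast
  mk <- function(freq, role, mask_c)
    data.frame(freq_hz = freq, role = role, target_c = tc,
               mask_c = mask_c, stringsAsFactors = FALSE)
  switch(config,
    monocular       = mk(2, "both", 0),
    binocular       = mk(2, "both", tc),
    dichoptic       = mk(2, "both", 48),
    monocular_cross = mk(1.6, "both", 0),
    binocular_cross = rbind(mk(2, "target", tc), mk(1.6, "mask", tc)),
    dichoptic_cross = rbind(mk(2, "target", 48), mk(1.6, "mask", 48)),
    stop("unknown ocular configuration '", config, "'"))
}

## Scalar model amplitude for one frequency row.
.rowAmplitude <- function(row, params) {
  both <- row$role == "both"
  a <- (both | row$role == "target") *
    channelResponse(row$target_c, row$mask_c, params)
  b <- (both | row$role == "mask") *
    channelResponse(row$mask_c, row$target_c, params)
  params@Rmax * (a + b) + params@n
}

#' Configuration for the amplitude-domain generator
#'
#' @param params \linkS4class{GainControlParams} of the generating model.
#' @param design Condition design (default: the full 6 configurations x
#'   5 contrasts factorial, see \code{\link{conditionDesign}}).
#' @param nParticipants Group size (default 30).
#' @param trialsPerCondition Repetitions per cell (default 6: three
#'   60-trial blocks over 30 cells).
#' @param noiseSd Trial-level complex noise SD per real/imaginary
#'   component, in response units.  The default \code{NULL} uses
#'   \code{n * sqrt(trialsPerCondition)}, so that the residual noise of a
#'   participant's trial-averaged amplitude equals the generating noise
#'   parameter — the level the model's likelihood assumes.
#' @param scaleSdLog Participant amplitude-scale SD on the natural-log
#'   scale (default 0.2).
#' @param phaseJitterSd Between-participant phase jitter, radians
#'   (default 0.3).  Phases must cluster across participants for the
#'   group-level coherent average to retain the signal, as the real
#'   pipeline assumes.
#' @param seed Integer seed.
#' @return Config list for \code{\link{generateAmplitudeDataset}}.
#' @export
ampConfig <- function(params, design = conditionDesign(),
                      nParticipants = 30, trialsPerCondition = 6,
                      noiseSd = NULL, scaleSdLog = 0.2,
                      phaseJitterSd = 0.3, seed = 1) {
  stopifnot(is(params, "GainControlParams"), !matchingMode(params))
  if (is.null(noiseSd)) noiseSd <- params@n * sqrt(trialsPerCondition)
  list(params = params, design = design, nParticipants = nParticipants,
       trialsPerCondition = trialsPerCondition, noiseSd = noiseSd,
       scaleSdLog = scaleSdLog, phaseJitterSd = phaseJitterSd,
       seed = seed)
}

#' Generate trial-level complex amplitudes
#'
#' Emulates the statistical structure the spectral pipeline assumes: each
#' trial's complex amplitude at each stimulated frequency equals a
#' participant-specific scale times the scalar model prediction, rotated
#' to the participant's common phase, plus isotropic complex Gaussian
#' trial noise.
#'
#' @param config From \code{\link{ampConfig}}.
#' @return data.frame with columns \code{participant}, \code{config},
#'   \code{contrast}, \code{freq_hz}, \code{role}, \code{target_c},
#'   \code{mask_c}, \code{trial}, \code{re}, \code{im}.
#' @export
generateAmplitudeDataset <- function(config) {
  set.seed(deriveSeed(config$seed, 101))
  params <- config$params
  nP <- config$nParticipants
  nT <- config$trialsPerCondition
  scales <- rlnorm(nP, 0, config$scaleSdLog)
  phases <- runif(1, 0, 2 * pi) + rnorm(nP, 0, config$phaseJitterSd)
  out <- list(); k <- 0
  for (i in seq_len(nrow(config$design))) {
    cfg <- config$design$config[i]
    con <- config$design$contrast[i]
    rows <- .conditionRows(cfg, con)
    for (r in seq_len(nrow(rows))) {
      row <- rows[r, ]
      A <- .rowAmplitude(row, params)
      for (p in seq_len(nP)) {
        z <- scales[p] * A * exp(1i * phases[p]) +
          rcnorm(nT, config$noiseSd)
        k <- k + 1
        out[[k]] <- data.frame(
          participant = p, config = cfg, contrast = con,
          freq_hz = row$freq_hz, role = row$role, harmonic = 1L,
          target_c = row$target_c, mask_c = row$mask_c,
          trial = seq_len(nT), re = Re(z), im = Im(z),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Per-participant coherent amplitudes
#'
#' Collapses trial-level complex amplitudes to one coherent mean per
#' participant and condition cell, with one Mahalanobis exclusion pass
#' over trials (the trial-to-participant averaging stage).
#'
#' @param ampData Output of \code{\link{generateAmplitudeDataset}} (or
#'   the analysis pipeline's equivalent).
#' @param filter Apply the Mahalanobis pass (default TRUE).
#' @return data.frame with one row per participant x cell x role:
#'   complex mean (\code{re}, \code{im}) and its modulus
#'   (\code{amplitude}), plus the design columns needed for fitting.
#' @export
participantAmplitudes <- function(ampData, filter = TRUE) {
  if (is.null(ampData$harmonic)) ampData$harmonic <- 1L
  key <- interaction(ampData$participant, ampData$config,
                     ampData$contrast, ampData$role, ampData$freq_hz,
                     drop = TRUE)
  rows <- lapply(split(ampData, key), function(d) {
    z <- complex(real = d$re, imaginary = d$im)
    zm <- if (filter) robustCoherentMean(z) else coherentMean(z)
    data.frame(participant = d$participant[1], config = d$config[1],
               contrast = d$contrast[1], freq_hz = d$freq_hz[1],
               role = d$role[1], harmonic = d$harmonic[1],
               target_c = d$target_c[1],
               mask_c = d$mask_c[1], re = Re(zm), im = Im(zm),
               amplitude = Mod(zm), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$config, out$contrast, out$role, out$freq_hz,
            out$participant), ]
}

#' Group-level coherent amplitudes with bootstrap errors
#'
#' Participant-to-group averaging stage: one Mahalanobis pass across
#' participants, coherent mean, and a participant-level bootstrap SE of
#' the modulus.
#'
#' @param partAmps Output of \code{\link{participantAmplitudes}}.
#' @param iterations Bootstrap iterations (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return data.frame per condition cell and role: \code{amplitude}
#'   (modulus of the group coherent mean), \code{se}, \code{nRetained}.
#' @export
groupAmplitudes <- function(partAmps, iterations = 1000, seed = 1) {
  if (is.null(partAmps$harmonic)) partAmps$harmonic <- 1L
  key <- interaction(partAmps$config, partAmps$contrast, partAmps$role,
                     partAmps$freq_hz, drop = TRUE)
  i <- 0
  rows <- lapply(split(partAmps, key), function(d) {
    z <- complex(real = d$re, imaginary = d$im)
    keep <- mahalanobisFilter(z)$retained
    i <<- i + 1
    se <- if (length(keep) >= 2)
      bootstrapSE(keep, iterations, seed = deriveSeed(seed, i))
    else NA_real_
    data.frame(config = d$config[1], contrast = d$contrast[1],
               freq_hz = d$freq_hz[1], role = d$role[1],
               harmonic = d$harmonic[1],
               target_c = d$target_c[1], mask_c = d$mask_c[1],
               amplitude = Mod(coherentMean(keep)), se = se,
               nRetained = length(keep), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$config, out$contrast, out$role, out$freq_hz), ]
}

#' Configuration for the raw time-series generator
#'
#' @inheritParams ampConfig
#' @param modality \code{"pupil"} (120 Hz, mm, two eye channels) or
#'   \code{"eeg"} (1000 Hz, microvolts, four occipital electrodes).
#' @param duration Trial duration in seconds (default 12, the stimulus
#'   presentation period).
#' @param broadbandSd White-noise SD per sample (default 0.03 mm pupil /
#'   5 microvolts EEG).
#' @param dropProb Per-sample dropped-frame probability (pupil only,
#'   default 0.02).
#' @param baseline Baseline level (default 6 mm pupil / 0 EEG).
#' @param onsetAmp,onsetTau Pupil onset constriction amplitude (mm) and
#'   exponential time constant (s); the 2-s epoch skip excludes most of
#'   this transient.
#' @return Config list for \code{\link{generateRawTrials}}.
#' @export
rawConfig <- function(modality = c("pupil", "eeg"), params,
                      design = conditionDesign(),
                      nParticipants = 2, trialsPerCondition = 2,
                      duration = 12,
                      broadbandSd = NULL, dropProb = 0.02,
                      baseline = NULL, onsetAmp = 0.4, onsetTau = 1,
                      scaleSdLog = 0.2, seed = 1) {
  modality <- match.arg(modality)
  stopifnot(is(params, "GainControlParams"), !matchingMode(params))
  rate <- if (modality == "pupil") 120 else 1000
  if (is.null(broadbandSd)) broadbandSd <- if (modality == "pupil") 0.03 else 5
  if (is.null(baseline)) baseline <- if (modality == "pupil") 6 else 0
  list(modality = modality, params = params, design = design,
       nParticipants = nParticipants,
       trialsPerCondition = trialsPerCondition, rate = rate,
       duration = duration, broadbandSd = broadbandSd,
       dropProb = dropProb, baseline = baseline, onsetAmp = onsetAmp,
       onsetTau = onsetTau, scaleSdLog = scaleSdLog, seed = seed)
}

#' Generate raw trial time series
#'
#' Builds trial traces as baseline + (pupil only) an exponential onset
#' constriction + model-amplitude sinusoids at the condition's stimulated
#' frequencies + broadband Gaussian noise, with dropped frames (\code{NA})
#' for the pupil modality.  The injected 2 Hz amplitude is recovered by
#' the epoch-then-spectrum path.
#'
#' @param config From \code{\link{rawConfig}}.
#' @return A \linkS4class{RecordingSet}.
#' @export
generateRawTrials <- function(config) {
  set.seed(deriveSeed(config$seed, 202))
  params <- config$params
  rate <- config$rate; dur <- config$duration
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  channels <- if (config$modality == "pupil") c("left", "right")
              else c("POz", "Oz", "O1", "O2")
  nC <- length(channels)
  scales <- rlnorm(config$nParticipants, 0, config$scaleSdLog)
  phases <- runif(1, 0, 2 * pi) + rnorm(config$nParticipants, 0, 0.3)
  trials <- list(); info <- list(); k <- 0
  for (p in seq_len(config$nParticipants)) {
    for (i in seq_len(nrow(config$design))) {
      cfg <- config$design$config[i]
      con <- config$design$contrast[i]
      rows <- .conditionRows(cfg, con)
      sig <- rep(0, length(t))
      for (r in seq_len(nrow(rows)))
        sig <- sig + scales[p] * .rowAmplitude(rows[r, ], params) *
          sin(2 * pi * rows$freq_hz[r] * t + phases[p])
      base <- config$baseline
      if (config$modality == "pupil")
        base <- base - config$onsetAmp * exp(-t / config$onsetTau)
      for (tr in seq_len(config$trialsPerCondition)) {
        m <- matrix(NA_real_, nC, length(t))
        for (ch in seq_len(nC)) {
          x <- base + sig + rnorm(length(t), 0, config$broadbandSd)
          if (config$modality == "pupil" && config$dropProb > 0)
            x[runif(length(t)) < config$dropProb] <- NA_real_
          m[ch, ] <- x
        }
        k <- k + 1
        trials[[k]] <- m
        info[[k]] <- data.frame(participant = p,
                                condition = paste0(cfg, "_", con),
                                trial = tr, stringsAsFactors = FALSE)
      }
    }
  }
  recordingSet(config$modality, rate, channels, trials,
               do.call(rbind, info))
}

#' Configuration for the matching-session generator
#'
#' @param params Matching-mode \linkS4class{GainControlParams} of the
#'   simulated observer.
#' @param standards Binocular standard contrasts (default 24 and 48\%).
#' @param ratios Interocular ratios (default 0, 0.25, 0.5, 0.75, 1;
#'   with left/right sides this yields the 9 distinct conditions).
#' @param repetitions Blocks per condition and standard (default 3).
#' @param nTrialsBlock Trials per block (default 50).
#' @param nParticipants Number of simulated observers (default 1).
#' @param seed Integer seed.
#' @return Config list for \code{\link{generateMatchingDataset}}.
#' @export
matchConfig <- function(params, standards = c(24, 48),
                        ratios = c(0, 0.25, 0.5, 0.75, 1),
                        repetitions = 3, nTrialsBlock = 50,
                        nParticipants = 1, seed = 1) {
  stopifnot(is(params, "GainControlParams"), matchingMode(params))
  list(params = params, standards = standards, ratios = ratios,
       repetitions = repetitions, nTrialsBlock = nTrialsBlock,
       nParticipants = nParticipants, seed = seed)
}

#' Generate a full matching session
#'
#' Runs the complete block design (repetitions x standards x 9 ratio/side
#' conditions, 50 trials each by default) through
#' \code{\link{simulateMatchingBlock}} for each simulated participant.
#'
#' @param config From \code{\link{matchConfig}}.
#' @return data.frame of trials with \code{participant} and \code{block}
#'   columns prepended to the per-trial schema.
#' @export
generateMatchingDataset <- function(config) {
  conds <- do.call(rbind, lapply(config$ratios, function(r) {
    if (r == 1) data.frame(ratio = r, side = "left")
    else data.frame(ratio = r, side = c("left", "right"))
  }))
  out <- list(); k <- 0; block <- 0
  for (p in seq_len(config$nParticipants)) {
    for (std in config$standards) {
      for (i in seq_len(nrow(conds))) {
        for (rep in seq_len(config$repetitions)) {
          block <- block + 1
          d <- simulateMatchingBlock(
            config$params, conds$ratio[i], std, side = conds$side[i],
            nTrialsBlock = config$nTrialsBlock,
            seed = deriveSeed(config$seed, 1000 + block))
          k <- k + 1
          out[[k]] <- cbind(data.frame(participant = p, block = block),
                            d)
        }
      }
    }
  }
  do.call(rbind, out)
}
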