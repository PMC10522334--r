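## End-to-end orchestration: simulate -> analyze -> fit, with manifests.
## These functions are the package's "commands": each takes a config (a
## plain list from the *Config() constructors) plus a seed, and every run
## is reproducible from its manifest.

.parseCondition <- function(condition) {
  ## condition labels are "<config>_<contrast>"; config names themselves
  ## contain underscores, so split on the final one
  m <- regmatches(condition, regexpr("_[0-9.]+$", condition))
  if (any(!lengths(regmatches(condition, gregexpr("_[0-9.]+$", condition)))))
    stop("cannot parse condition label(s)")
  contrast <- as.numeric(sub("^_", "", m))
  config <- substr(condition, 1, nchar(condition) - nchar(m))
  data.frame(config = config, contrast = contrast, stringsAsFactors = FALSE)
}

#' Spectral analysis of a RecordingSet
#'
#' Runs the fixed preprocessing order on every trial: (read) ->
#' interpolate dropped frames (pupil) -> epoch -> amplitude spectrum ->
#' pool eyes (pupil) or average occipital electrodes (EEG), extracting
#' the complex amplitude at each frequency the trial's condition
#' stimulates.  The 5 Hz display filter is never part of this path.
#' Trials with unrepairable gaps are dropped and counted.
#'
#' @param rs A \linkS4class{RecordingSet} whose condition labels follow
#'   \code{"<config>_<contrast>"}.
#' @param skip,keep Epoching parameters in seconds (defaults 2 and 10).
#' @param maxGap Longest repairable gap, seconds (pupil).
#' @return Trial-level amplitude data.frame (same schema as
#'   \code{\link{generateAmplitudeDataset}}), with attributes
#'   \code{pipeline} (ordered character vector of stages applied) and
#'   \code{droppedTrials}.
#' @export
analyzeRecordingSet <- function(rs, skip = 2, keep = 10, maxGap = 0.5) {
  stopifnot(is(rs, "RecordingSet"))
  info <- trialInfo(rs)
  parsed <- .parseCondition(info$condition)
  pupil <- modality(rs) == "pupil"
  stages <- c("read", if (pupil) "interpolate", "epoch", "spectrum",
              if (pupil) "pool_eyes" else "average_electrodes")
  dropped <- 0L
  out <- list(); k <- 0
  for (i in seq_len(nTrials(rs))) {
    rows <- .conditionRows(parsed$config[i], parsed$contrast[i])
    rows$harmonic <- 1L
    if (!pupil) {
      ## cortical responses carry energy at the second harmonic too
      h2 <- rows; h2$freq_hz <- 2 * h2$freq_hz; h2$harmonic <- 2L
      rows <- rbind(rows, h2)
    }
    fr <- unique(rows$freq_hz[rows$harmonic == 1L])
    if (length(fr) == 2) {
      ## cross-frequency condition: intermodulation sum/difference bins
      im <- rows[1:2, ]
      im$freq_hz <- round(c(sum(fr), abs(diff(fr))), 6)
      im$role <- c("im_sum", "im_diff")
      im$harmonic <- 1L
      rows <- rbind(rows, im)
    }
    tr <- trialMatrix(rs, i)
    chanAmps <- vector("list", nrow(tr))
    ok <- TRUE
    for (ch in seq_len(nrow(tr))) {
      x <- tr[ch, ]
      if (pupil) {
        x <- interpolateGaps(x, samplingRate(rs), maxGap)
        if (!attr(x, "usable")) { ok <- FALSE; break }
      } else if (anyNA(x)) { ok <- FALSE; break }
      sp <- amplitudeSpectrum(epochTrial(x, samplingRate(rs), skip, keep))
      chanAmps[[ch]] <- vapply(rows$freq_hz, function(f) binAt(sp, f),
                               complex(1))
    }
    if (!ok) { dropped <- dropped + 1L; next }
    amps <- do.call(rbind, chanAmps) # channels x frequency rows
    emit <- function(r, z, trialLabel) {
      k <<- k + 1
      out[[k]] <<- data.frame(
        participant = info$participant[i], config = parsed$config[i],
        contrast = parsed$contrast[i], freq_hz = rows$freq_hz[r],
        role = rows$role[r], harmonic = rows$harmonic[r],
        target_c = rows$target_c[r],
        mask_c = rows$mask_c[r], trial = trialLabel,
        re = Re(z), im = Im(z), stringsAsFactors = FALSE)
    }
    if (pupil) {
      ## pool eyes: each eye's amplitude is a separate entry in the pool
      for (ch in seq_len(nrow(amps))) for (r in seq_len(nrow(rows)))
        emit(r, amps[ch, r],
             paste0(info$trial[i], "_", channelNames(rs)[ch]))
    } else {
      for (r in seq_len(nrow(rows)))
        emit(r, averageElectrodes(setNames(amps[, r], channelNames(rs))),
             as.character(info$trial[i]))
    }
  }
  res <- do.call(rbind, out)
  structure(res, pipeline = stages, droppedTrials = dropped)
}

#' Per-participant binocular:monocular summation ratios in dB
#'
#' Computes \code{\link{ratioDb}} per participant and contrast (binocular
#' over monocular amplitude at the target frequency), then averages
#' across participants with a bootstrap SE.
#'
#' @param partAmps Output of \code{\link{participantAmplitudes}}.
#' @param iterations,seed Bootstrap settings.
#' @return data.frame: \code{contrast}, \code{ratio_db} (participant
#'   mean), \code{se_db}, \code{n}.
#' @export
summationRatios <- function(partAmps, iterations = 1000, seed = 1) {
  if (is.null(partAmps$harmonic)) partAmps$harmonic <- 1L
  d <- partAmps[partAmps$role == "both" & partAmps$harmonic == 1L &
                partAmps$config %in% c("monocular", "binocular"), ]
  contrasts <- sort(unique(d$contrast))
  rows <- lapply(seq_along(contrasts), function(i) {
    con <- contrasts[i]
    b <- d[d$config == "binocular" & d$contrast == con, ]
    m <- d[d$config == "monocular" & d$contrast == con, ]
    common <- intersect(b$participant, m$participant)
    r <- ratioDb(b$amplitude[match(common, b$participant)],
                 m$amplitude[match(common, m$participant)])
    r <- r[is.finite(r)]
    data.frame(contrast = con, ratio_db = mean(r),
               se_db = if (length(r) >= 2)
                 bootstrapSE(r, iterations, seed = deriveSeed(seed, i))
               else NA_real_,
               n = length(r))
  })
  do.call(rbind, rows)
}

#' Condition-by-contrast ANOVA2circ on participant amplitudes
#'
#' Runs \code{\link{anova2circ}} on the per-participant complex means of
#' the requested configurations at the target frequency (the standard
#' comparison is monocular vs binocular across the five contrasts).
#'
#' @param partAmps Output of \code{\link{participantAmplitudes}}.
#' @param configs Configurations to compare.
#' @param subject Pass participants as a subject factor to use the
#'   repeated-measures error stratum (default FALSE: within-cell error).
#' @return data.frame of effects from \code{\link{anova2circ}}.
#' @export
conditionAnova <- function(partAmps,
                           configs = c("monocular", "binocular"),
                           subject = FALSE) {
  if (is.null(partAmps$harmonic)) partAmps$harmonic <- 1L
  d <- partAmps[partAmps$role %in% c("both", "target") &
                partAmps$harmonic == 1L & partAmps$config %in% configs, ]
  z <- complex(real = d$re, imaginary = d$im)
  fac <- data.frame(condition = d$config, contrast = d$contrast)
  if (length(configs) == 1L) fac <- fac["contrast"]
  anova2circ(z, fac, subject = if (subject) d$participant else NULL)
}

#' Simulate a full synthetic study
#'
#' Writes the three dataset families (trial amplitudes, raw trials,
#' matching sessions) plus a manifest recording the configuration and
#' seed, so the run is reproducible.
#'
#' @param config List with elements \code{amp} (\code{\link{ampConfig}}),
#'   \code{raw} (\code{\link{rawConfig}}), \code{matching}
#'   (\code{\link{matchConfig}}); any subset may be present.
#' @param outDir Output directory.
#' @param overwrite Refuse to write into an existing manifest's directory
#'   unless TRUE.
#' @return \code{outDir}, invisibly.
#' @export
runSimulation <- function(config, outDir, overwrite = FALSE) {
  manifest <- file.path(outDir, "manifest.yaml")
  if (file.exists(manifest) && !overwrite)
    stop("output directory already holds a run; use overwrite = TRUE")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  if (!is.null(config$amp)) {
    write.csv(generateAmplitudeDataset(config$amp),
              file.path(outDir, "amplitudes.csv"), row.names = FALSE)
    written <- c(written, "amplitudes.csv")
  }
  if (!is.null(config$raw)) {
    writeTrialsCsv(generateRawTrials(config$raw),
                   file.path(outDir, "raw_trials.csv"))
    written <- c(written, "raw_trials.csv")
  }
  if (!is.null(config$matching)) {
    write.csv(generateMatchingDataset(config$matching),
              file.path(outDir, "matching.csv"), row.names = FALSE)
    written <- c(written, "matching.csv")
  }
  describe <- function(cfg) {
    if (is.null(cfg)) return(NULL)
    lapply(cfg, function(v) {
      if (is(v, "GainControlParams"))
        list(Z = v@Z, w = v@w, n = v@n, Rmax = v@Rmax)
      else if (is.data.frame(v)) sprintf("<data.frame %d rows>", nrow(v))
      else v
    })
  }
  yaml::write_yaml(list(
    package = "ssflicker",
    version = as.character(utils::packageVersion("ssflicker")),
    files = as.list(written),
    config = list(amp = describe(config$amp), raw = describe(config$raw),
                  matching = describe(config$matching))),
    manifest)
  invisible(outDir)
}

#' Analyze a simulated (or recorded) dataset directory
#'
#' Loads whichever dataset families are present and produces the summary
#' tables: group contrast-response amplitudes with bootstrap SEs,
#' per-participant summation ratios in dB, and the complex-domain ANOVA
#' comparing monocular and binocular conditions.
#'
#' @param dir Directory written by \code{\link{runSimulation}}.
#' @param seed Integer seed for the bootstrap resampling.
#' @return List with elements \code{amplitudes} (group table),
#'   \code{ratios}, \code{anova}, and (when raw trials are present)
#'   \code{rawAmplitudes}; missing families produce a warning and a
#'   partial result.
#' @export
runAnalysis <- function(dir, seed = 1) {
  out <- list()
  ampPath <- file.path(dir, "amplitudes.csv")
  rawPath <- file.path(dir, "raw_trials.csv")
  if (file.exists(ampPath)) {
    amps <- read.csv(ampPath, stringsAsFactors = FALSE)
    part <- participantAmplitudes(amps)
    out$amplitudes <- groupAmplitudes(part, seed = deriveSeed(seed, 1))
    out$ratios <- summationRatios(part, seed = deriveSeed(seed, 2))
    out$anova <- conditionAnova(part)
  } else {
    warning("no amplitudes.csv in ", dir, "; partial analysis")
  }
  if (file.exists(rawPath)) {
    rs <- readTrialsCsv(rawPath)
    out$rawAmplitudes <- analyzeRecordingSet(rs)
  }
  out
}

#' Fit the gain-control model to an analyzed dataset
#'
#' Thin wrapper over \code{\link{samplePosterior}} that accepts either a
#' participant-amplitude table or a matching-trials table and returns the
#' posterior fit plus a one-row summary of parameter medians (the shape
#' of the published parameter tables; Rmax is absent for matching data).
#'
#' @param data Amplitude table (\code{\link{participantAmplitudes}}) or
#'   matching trials (\code{\link{generateMatchingDataset}}).
#' @param kind Dataset kind; \code{"matching"} switches likelihood and
#'   drops Rmax.
#' @param ... Passed to \code{\link{samplePosterior}}.
#' @return List with \code{fit} (a \linkS4class{PosteriorFit}) and
#'   \code{table} (one-row data.frame of medians: Z, n, w, and Rmax when
#'   present).
#' @export
runFit <- function(data, kind, ...) {
  if (kind != "matching") {
    ## keep only rows the scalar model predicts: fundamental bins for 1F
    ## fits, second-harmonic bins for the 2F fit; IM bins are
    ## summary-table output, not fit input
    if (is.null(data$harmonic)) data$harmonic <- 1L
    wantH <- if (kind == "eeg_2f") 2L else 1L
    data <- data[data$harmonic == wantH &
                 data$role %in% c("both", "target", "mask"), ]
    if (!nrow(data)) stop("no rows of the requested kind in the data")
  }
  fit <- samplePosterior(data, kind = kind, ...)
  s <- posteriorSummary(fit)
  med <- setNames(s$median, s$param)
  tab <- data.frame(dataset = kind, Z = med[["Z"]], n = med[["n"]],
                    w = med[["w"]],
                    Rmax = if ("Rmax" %in% names(med)) med[["Rmax"]]
                           else NA_real_,
                    converged = isConverged(fit))
  list(fit = fit, table = tab)
}
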