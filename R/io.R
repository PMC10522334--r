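## Readers and preprocessors for pupil / EEG trial CSVs.
##
## On-disk format: long CSV with columns
##   participant, condition, trial, channel, sample_index, value
## plus a YAML sidecar (<path>.meta.yaml) recording modality, sampling
## rate and onset index.  No proprietary eye-tracker or EEG formats.

.sidecarPath <- function(path) paste0(path, ".meta.yaml")

#' Write a RecordingSet to a long-format CSV (plus metadata sidecar)
#'
#' @param x A \linkS4class{RecordingSet}.
#' @param path Output CSV path; a \code{<path>.meta.yaml} sidecar is
#'   written alongside.
#' @return \code{path}, invisibly.
#' @export
writeTrialsCsv <- function(x, path) {
  stopifnot(is(x, "RecordingSet"))
  info <- trialInfo(x)
  rows <- lapply(seq_len(nTrials(x)), function(i) {
    tr <- x@trials[[i]]
    ns <- ncol(tr)
    data.frame(participant = info$participant[i],
               condition = info$condition[i],
               trial = info$trial[i],
               channel = rep(x@channels, each = ns),
               sample_index = rep(seq_len(ns), length(x@channels)),
               value = as.vector(t(tr)),
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  yaml::write_yaml(list(modality = modality(x), rate = samplingRate(x),
                        onset_index = 1L, channels = as.list(x@channels)),
                   .sidecarPath(path))
  invisible(path)
}

#' Read trial time series from a long-format CSV
#'
#' Parses the long schema back into a \linkS4class{RecordingSet}.  Row
#' order in the file is irrelevant (the schema is keyed).  Missing samples
#' remain \code{NA}, never silently dropped; schema violations raise a
#' parse error naming the offending column or row.
#'
#' @param path CSV path (with its \code{.meta.yaml} sidecar).
#' @param modality Override for the sidecar modality, if needed.
#' @return A \linkS4class{RecordingSet}.
#' @export
readTrialsCsv <- function(path, modality = NULL) {
  meta <- yaml::read_yaml(.sidecarPath(path))
  modality <- modality %||% meta$modality
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "condition", "trial", "channel",
            "sample_index", "value")
  missingCols <- setdiff(need, names(d))
  if (length(missingCols))
    stop("parse error: missing column(s) ", paste(missingCols, collapse = ", "))
  if (!is.numeric(d$sample_index))
    stop("parse error: sample_index must be numeric")
  bad <- which(!is.finite(d$sample_index))
  if (length(bad))
    stop("parse error at row ", bad[1], ": bad sample_index")
  channels <- unlist(meta$channels) %||% sort(unique(d$channel))
  key <- interaction(d$participant, d$condition, d$trial, drop = TRUE)
  ns <- max(d$sample_index)
  ord <- unique(data.frame(participant = d$participant,
                           condition = d$condition, trial = d$trial,
                           key = as.character(key),
                           stringsAsFactors = FALSE))
  ## canonical trial order, independent of row order in the file
  ord <- ord[order(ord$participant, ord$condition, ord$trial), ]
  rownames(ord) <- NULL
  trials <- lapply(ord$key, function(k) {
    rows <- d[as.character(key) == k, ]
    tr <- matrix(NA_real_, nrow = length(channels), ncol = ns)
    ci <- match(rows$channel, channels)
    if (anyNA(ci))
      stop("parse error: unknown channel '",
           rows$channel[which(is.na(ci))[1]], "'")
    tr[cbind(ci, rows$sample_index)] <- rows$value
    tr
  })
  recordingSet(modality, meta$rate, channels, trials,
               ord[c("participant", "condition", "trial")])
}

#' Interpolate dropped frames in a trace
#'
#' Linearly interpolates across runs of \code{NA} samples (dropped or
#' missing eye-tracker frames) so that sampling is regular and continuous.
#' A gap longer than \code{maxGap} seconds cannot be repaired credibly:
#' the trace is returned unchanged with attribute \code{usable = FALSE}.
#'
#' @param trace Numeric vector with \code{NA} marking missing samples.
#' @param rate Sampling rate, samples/s.
#' @param maxGap Longest repairable gap in seconds (default 0.5, a
#'   typical blink).
#' @return Numeric trace with attribute \code{usable} (logical).
#' @export
interpolateGaps <- function(trace, rate, maxGap = 0.5) {
  nas <- is.na(trace)
  if (!any(nas)) return(structure(trace, usable = TRUE))
  r <- rle(nas)
  if (any(r$values & r$lengths > maxGap * rate))
    return(structure(trace, usable = FALSE))
  if (all(nas)) return(structure(trace, usable = FALSE))
  idx <- seq_along(trace)
  out <- approx(idx[!nas], trace[!nas], xout = idx, rule = 2)$y
  structure(out, usable = TRUE)
}

#' Pool spectral estimates across the eyes
#'
#' Concatenates per-trial complex amplitudes from the two eyes into one
#' trial pool.  Pooling happens at the complex-amplitude level, before
#' coherent averaging; it is justified when the consensual pupil response
#' is complete, so both eyes carry the same signal.
#'
#' @param left,right Complex vectors (per-trial amplitudes for one eye);
#'   either may be empty.
#' @return Complex vector of pooled amplitudes.
#' @export
poolEyes <- function(left, right) {
  c(as.complex(left), as.complex(right))
}

#' Coherent average across occipital electrodes
#'
#' Complex mean of per-electrode spectral amplitudes over a named
#' electrode subset (default: the four occipital electrodes POz, Oz, O1,
#' O2).
#'
#' @param spectra Named complex vector or named list of complex scalars,
#'   one entry per electrode.
#' @param names Electrodes to average.
#' @return Complex scalar.
#' @export
averageElectrodes <- function(spectra,
                              names = c("POz", "Oz", "O1", "O2")) {
  if (is.list(spectra)) spectra <- unlist(spectra)
  absent <- setdiff(names, base::names(spectra))
  if (length(absent))
    stop("missing electrode(s): ", paste(absent, collapse = ", "))
  coherentMean(spectra[names])
}

#' Low-pass filter for waveform display
#'
#' Zero-phase 4th-order Butterworth low-pass (applied forward and
#' backward) used only when plotting average waveforms; it is never part
#' of the spectral analysis path.  With the default 5 Hz cutoff a 2 Hz
#' component passes within 1\% while components above 20 Hz are strongly
#' attenuated.
#'
#' @param trace Numeric vector.
#' @param rate Sampling rate, samples/s (must exceed twice the cutoff).
#' @param cutoff Cutoff frequency, Hz (default 5).
#' @return Filtered trace.
#' @export
lowpassDisplay <- function(trace, rate, cutoff = 5) {
  if (cutoff >= rate / 2)
    stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(4, cutoff / (rate / 2), type = "low")
  ## odd-reflection padding tames the forward-backward pass's edge
  ## transients (about one cutoff period each side)
  n <- length(trace)
  p <- min(n - 1, ceiling(3 * rate / cutoff))
  xp <- c(2 * trace[1] - trace[(p + 1):2],
          trace,
          2 * trace[n] - trace[(n - 1):(n - p)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(p + 1):(p + n)]
}
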