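## Steady-state spectral analysis: epoching, Fourier decomposition with a
## sine-amplitude scaling convention, coherent (complex-domain) averaging
## with Mahalanobis outlier exclusion, dB summation ratios and bootstrap
## standard errors.

#' Extract the analysis epoch from a raw trial
#'
#' Cuts the steady-state analysis window out of a raw trial trace:
#' the first \code{skip} seconds after stimulus onset are discarded (onset
#' transient) and exactly \code{keep} seconds are retained.  With the
#' defaults, a 12-s stimulus yields a 10-s epoch whose spectral resolution
#' is 0.1 Hz.
#'
#' @param raw Numeric vector of samples (or a channels x samples matrix).
#' @param rate Sampling rate, samples/s.
#' @param skip Seconds to drop after onset (default 2).
#' @param keep Epoch duration in seconds (default 10).
#' @return Vector (or matrix) of exactly \code{keep * rate} samples,
#'   with attributes \code{rate} and \code{duration}.
#' @export
epochTrial <- function(raw, rate, skip = 2, keep = 10) {
  n <- if (is.matrix(raw)) ncol(raw) else length(raw)
  need <- (skip + keep) * rate
  if (n < need)
    stop(sprintf("truncated trial: %d samples, need %d (%g s at %g Hz)",
                 n, ceiling(need), skip + keep, rate))
  idx <- seq.int(skip * rate + 1, (skip + keep) * rate)
  out <- if (is.matrix(raw)) raw[, idx, drop = FALSE] else raw[idx]
  structure(out, rate = rate, duration = keep)
}

#' Amplitude spectrum with sine-amplitude scaling
#'
#' Fourier transform of an epoch, scaled so that a pure sinusoid
#' \eqn{A\sin(2\pi f t + \phi)} with an integer number of cycles in the
#' window yields a bin of modulus exactly \eqn{A} at \eqn{f} (scaling
#' \code{2/N} for non-DC bins, \code{1/N} at DC).  Under this convention
#' the time-domain variance equals \eqn{\sum A_k^2/2} over non-DC bins
#' (Parseval).
#'
#' @param epoch Numeric vector from \code{\link{epochTrial}}, or any
#'   vector if \code{rate} is given.
#' @param rate Sampling rate; taken from the epoch attribute if absent.
#' @return A \linkS4class{SpectralEstimate} covering DC to Nyquist.
#' @export
amplitudeSpectrum <- function(epoch, rate = attr(epoch, "rate")) {
  if (is.null(rate)) stop("sampling rate unknown; pass rate=")
  if (anyNA(epoch))
    stop("epoch contains NA samples; interpolate gaps before analysis")
  x <- as.numeric(epoch)
  n <- length(x)
  ft <- fft(x)
  nbin <- floor(n / 2) + 1
  amp <- ft[seq_len(nbin)] / n
  amp[-1] <- 2 * amp[-1]
  freq <- (seq_len(nbin) - 1) * rate / n
  new("SpectralEstimate", amp = amp, freq = freq, rate = rate,
      duration = n / rate)
}

#' Coherent (complex-domain) mean
#'
#' Arithmetic mean of complex Fourier coefficients.  Averaging in the
#' complex domain retains phase, so phase-inconsistent noise cancels while
#' stimulus-locked components survive.
#'
#' @param values Complex vector (non-empty).
#' @return Complex scalar.
#' @export
coherentMean <- function(values) {
  if (!length(values)) stop("cannot average an empty set")
  mean(as.complex(values))
}

#' Mahalanobis outlier exclusion in the complex plane
#'
#' Treats complex amplitudes as (real, imaginary) pairs and removes points
#' whose Mahalanobis distance from the sample mean exceeds a threshold
#' (default D = 3), using the sample covariance of the retained stage's
#' input.  One pass is made per averaging stage; the filter is never
#' iterated to convergence.  Fewer than \code{minPoints} observations pass
#' through unfiltered (the covariance is too unstable to trust), and a
#' singular covariance falls back to pooled isotropic variance.
#'
#' @param values Complex vector.
#' @param threshold Distance cut-off (default 3).
#' @param minPoints Below this many points no exclusion is attempted.
#' @return List with \code{retained} (complex vector), \code{excluded}
#'   (integer indices into \code{values}) and \code{distances}.
#' @export
mahalanobisFilter <- function(values, threshold = 3, minPoints = 5) {
  values <- as.complex(values)
  m <- length(values)
  if (m < minPoints)
    return(list(retained = values, excluded = integer(0),
                distances = rep(NA_real_, m)))
  xy <- cbind(Re(values), Im(values))
  ctr <- colMeans(xy)
  S <- stats::cov(xy)
  d2 <- tryCatch(
    stats::mahalanobis(xy, ctr, S),
    error = function(e) NULL)
  if (is.null(d2) || !all(is.finite(d2)) || det(S) < .Machine$double.eps) {
    ## singular covariance: pooled isotropic variance fallback
    s2 <- mean(diag(S))
    if (s2 <= 0) # all points identical: nothing to exclude
      return(list(retained = values, excluded = integer(0),
                  distances = rep(0, m)))
    d2 <- rowSums(sweep(xy, 2, ctr)^2) / s2
  }
  d <- sqrt(d2)
  bad <- which(d > threshold)
  list(retained = values[setdiff(seq_len(m), bad)], excluded = bad,
       distances = d)
}

#' Coherent mean with one outlier-exclusion pass
#'
#' Convenience wrapper: applies \code{\link{mahalanobisFilter}} once, then
#' \code{\link{coherentMean}} to the retained points.
#'
#' @inheritParams mahalanobisFilter
#' @return Complex scalar mean of the retained points.
#' @export
robustCoherentMean <- function(values, threshold = 3, minPoints = 5) {
  coherentMean(mahalanobisFilter(values, threshold, minPoints)$retained)
}

#' Binocular:monocular ratio in decibels
#'
#' \code{20 * log10(binoc / monoc)}.  Ratios are computed per participant
#' before averaging, never on group means.
#'
#' @param binoc,monoc Non-negative amplitudes (vectorised).  A
#'   non-positive monocular amplitude yields \code{NA} with a warning
#'   (that participant's cell is dropped).
#' @return Numeric dB ratios.
#' @export
ratioDb <- function(binoc, monoc) {
  out <- rep(NA_real_, length(binoc))
  ok <- is.finite(monoc) & monoc > 0 & is.finite(binoc) & binoc > 0
  if (any(!ok))
    warning("non-positive amplitude(s): ratio undefined, cell dropped")
  out[ok] <- 20 * log10(binoc[ok] / monoc[ok])
  out
}

#' Bootstrap standard error across participants
#'
#' Resamples participants with replacement (top level only, never trials)
#' and returns the standard deviation of the resampled means.  Works on
#' real or complex values; for complex input the SE of the modulus of the
#' coherent mean is returned.
#'
#' @param values Per-participant values (numeric or complex), length >= 2.
#' @param iterations Bootstrap iterations (default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric standard error.
#' @export
bootstrapSE <- function(values, iterations = 1000, seed = NULL) {
  n <- length(values)
  if (n < 2) stop("need at least 2 participants")
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n, n * iterations, replace = TRUE), nrow = n)
  stat <- if (is.complex(values)) {
    vapply(seq_len(iterations),
           function(i) Mod(mean(values[idx[, i]])), numeric(1))
  } else {
    colMeans(matrix(values[idx], nrow = n))
  }
  sd(stat)
}
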