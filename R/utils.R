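#' Convert between percent contrast and decibels
#'
#' Contrast levels are expressed in decibels re 1\% Michelson contrast:
#' \code{dB = 20 * log10(pct)}.  The two functions are exact inverses.
#'
#' @param db Contrast in dB re 1\%.
#' @param pct Contrast in percent.
#' @return Numeric vector of converted values.
#' @examples
#' dbToPct(pctToDb(48))  # 48
#' @export
dbToPct <- function(db) 10^(db / 20)

#' @rdname dbToPct
#' @export
pctToDb <- function(pct) {
  if (any(pct <= 0)) stop("contrast must be positive to express in dB")
  20 * log10(pct)
}

## Counter-based seed derivation: one top-level seed is expanded to
## per-stage seeds so each pipeline stage is reproducible independently
## of execution order.  Kept below 2^31 (R integers are 32-bit).
deriveSeed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index))
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

## Isotropic complex Gaussian draws: sd applies per real/imag component.
rcnorm <- function(n, sd = 1) {
  complex(real = rnorm(n, 0, sd), imaginary = rnorm(n, 0, sd))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
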