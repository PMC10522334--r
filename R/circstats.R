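## Complex-domain test statistics for steady-state Fourier coefficients.
##
## Both tests assume the noise is isotropic in the complex plane (equal
## variance of the real and imaginary components, no correlation): the
## condition under which stimulus-absent Fourier coefficients of a real
## signal are circularly Gaussian.

#' T2circ test for a non-zero complex mean
#'
#' Tests whether a sample of complex Fourier coefficients has zero mean,
#' assuming isotropic complex Gaussian noise.  With \eqn{M} observations
#' \eqn{z_i} and sample mean \eqn{\bar z}, the statistic
#' \deqn{T^2_{circ} = \frac{M(M-1)\,|\bar z|^2}{\sum_i |z_i - \bar z|^2}}
#' is distributed as \eqn{F(2, 2M-2)} under the null: the real and
#' imaginary parts contribute one numerator and \eqn{M-1} denominator
#' degrees of freedom each.
#'
#' @param values Complex vector, length >= 2.
#' @return An object of class \code{"htest"} with the statistic, the
#'   degrees-of-freedom pair and the p-value.  Zero within-sample variance
#'   with a non-zero mean yields an infinite statistic and p = 0 (flagged
#'   with a warning); all-identical zero values are a degenerate input and
#'   raise an error.
#' @examples
#' set.seed(1)
#' z <- complex(real = rnorm(20, 1), imaginary = rnorm(20))
#' tcirc2(z)
#' @export
tcirc2 <- function(values) {
  z <- as.complex(values)
  M <- length(z)
  if (M < 2) stop("need at least 2 complex observations")
  zbar <- mean(z)
  ssw <- sum(Mod(z - zbar)^2)
  df1 <- 2
  df2 <- 2 * M - 2
  if (ssw == 0) {
    if (Mod(zbar) == 0)
      stop("degenerate input: all observations are identically zero")
    warning("zero within-sample variance: infinite statistic")
    stat <- Inf; p <- 0
  } else {
    stat <- M * (M - 1) * Mod(zbar)^2 / ssw
    p <- pf(stat, df1, df2, lower.tail = FALSE)
  }
  structure(list(
    statistic = c(Tcirc2 = stat),
    parameter = c(df1 = df1, df2 = df2),
    p.value = p,
    estimate = c(`|mean|` = Mod(zbar)),
    method = "T2circ test for non-zero complex mean",
    data.name = deparse(substitute(values))),
    class = "htest")
}

#' ANOVA2circ: factorial ANOVA on complex Fourier coefficients
#'
#' Multivariate extension of (repeated-measures) ANOVA to complex-valued
#' data, assuming equal variance of the real and imaginary components.
#' Sums of squares are squared complex moduli of the usual effect
#' contrasts; every degree-of-freedom count is doubled relative to the
#' univariate analysis because each observation contributes a real and an
#' imaginary component.  For a 2-condition x 5-contrast design with N = 30
#' participants the contrast main effect has the df pair (8, 580).
#'
#' By default the error stratum is the within-cell residual (df
#' \eqn{2(N_{obs} - cells)}).  Supplying \code{subject} removes the
#' subject main effect from the error (the repeated-measures stratum, df
#' reduced by \eqn{2(s-1)}).
#'
#' @param values Complex vector of coefficients, one per observation.
#' @param factors data.frame (or single factor) with one or two design
#'   factors, one row per observation.  The design must be balanced.
#' @param subject Optional subject identifier (factor/vector) to remove
#'   between-subject variance from the error stratum.
#' @return data.frame with one row per effect: \code{effect},
#'   \code{statistic}, \code{df1}, \code{df2}, \code{p}.
#' @export
anova2circ <- function(values, factors, subject = NULL) {
  z <- as.complex(values)
  if (is.data.frame(factors)) fl <- lapply(factors, factor)
  else fl <- list(factor1 = factor(factors))
  fl <- lapply(fl, factor)
  if (!length(fl) %in% 1:2)
    stop("one or two design factors supported")
  if (any(vapply(fl, length, 1L) != length(z)))
    stop("factors must have one entry per observation")
  cell <- interaction(fl, drop = FALSE)
  counts <- table(cell)
  if (length(unique(as.integer(counts))) != 1L || any(counts == 0))
    stop("unbalanced design: all cells must have the same number of observations")
  N <- length(z)
  ncell <- length(levels(cell))
  grand <- mean(z)

  ssEffect <- function(groups) {
    gm <- tapply(z, groups, mean)
    cnt <- table(groups)
    sum(as.numeric(cnt) * Mod(gm[names(cnt)] - grand)^2)
  }
  cellMeans <- tapply(z, cell, mean)
  ssErr <- sum(Mod(z - cellMeans[as.character(cell)])^2)
  dfErrU <- N - ncell

  if (!is.null(subject)) {
    subj <- factor(subject)
    if (length(subj) != N) stop("subject must have one entry per observation")
    ssSub <- ssEffect(subj)
    ssErr <- ssErr - ssSub
    ## guard: subject variance cannot exceed the residual it is carved from
    if (ssErr < 0) stop("subject stratum exceeds residual; check the design")
    dfErrU <- dfErrU - (nlevels(subj) - 1L)
  }
  if (dfErrU <= 0) stop("no residual degrees of freedom")

  effects <- list()
  nm <- names(fl)
  if (length(fl) == 1L) {
    effects[[nm[1]]] <- list(ss = ssEffect(fl[[1]]),
                             dfU = nlevels(fl[[1]]) - 1L)
  } else {
    a <- fl[[1]]; b <- fl[[2]]
    ssA <- ssEffect(a); ssB <- ssEffect(b)
    ssCells <- sum(as.numeric(counts) * Mod(cellMeans - grand)^2)
    ssAB <- ssCells - ssA - ssB
    effects[[nm[1]]] <- list(ss = ssA, dfU = nlevels(a) - 1L)
    effects[[nm[2]]] <- list(ss = ssB, dfU = nlevels(b) - 1L)
    effects[[paste0(nm[1], ":", nm[2])]] <-
      list(ss = max(ssAB, 0), dfU = (nlevels(a) - 1L) * (nlevels(b) - 1L))
  }

  out <- do.call(rbind, lapply(names(effects), function(e) {
    eff <- effects[[e]]
    df1 <- 2L * eff$dfU
    df2 <- 2L * dfErrU
    f <- (eff$ss / df1) / (ssErr / df2)
    data.frame(effect = e, statistic = f, df1 = df1, df2 = df2,
               p = pf(f, df1, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
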