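## Hierarchical Bayesian estimation of the gain-control parameters.
##
## A single group-level parameter set (Z, w, n, and Rmax for amplitude
## data) is fitted to the pooled individual data: a Student-t likelihood
## for steady-state amplitudes, a Bernoulli (probit) likelihood for
## single-trial matching responses.  Priors are positive-truncated
## Gaussians.  Sampling is by adaptive random-walk Metropolis on the log
## scale, with split R-hat and effective-sample-size diagnostics.

#' Prior specification
#'
#' Positive-truncated Gaussian priors for the model parameters: mean 1
#' and SD 0.5 for \code{w} and \code{Rmax}, mean 5 and SD 2 for \code{Z}
#' and \code{n}.
#'
#' @return data.frame with columns \code{param}, \code{mean}, \code{sd}.
#' @export
priorSpec <- function() {
  data.frame(param = c("Z", "w", "n", "Rmax"),
             mean = c(5, 1, 5, 1),
             sd = c(2, 0.5, 2, 0.5),
             stringsAsFactors = FALSE)
}

## Precompute the pieces of the vectorised amplitude predictor.
## `role` says which channels feed a row's spectral bin: "both" for
## same-frequency stimulation (the two channel responses sum in one bin),
## "target"/"mask" for the frequency-resolved cross conditions.
.ampTerms <- function(data) {
  need <- c("amplitude", "target_c", "mask_c", "role")
  if (!all(need %in% names(data)))
    stop("amplitude data needs columns ", paste(need, collapse = ", "))
  if (!all(data$role %in% c("both", "target", "mask")))
    stop("role must be 'both', 'target' or 'mask'")
  list(y = data$amplitude, tc = data$target_c, mc = data$mask_c,
       useT = as.numeric(data$role != "mask"),
       useM = as.numeric(data$role != "target"))
}

.ampPredict <- function(terms, Z, w, n, Rmax) {
  Rmax * (terms$useT * terms$tc^2 / (Z + terms$tc + w * terms$mc) +
          terms$useM * terms$mc^2 / (Z + terms$mc + w * terms$tc)) + n
}

#' Student-t log likelihood for steady-state amplitudes
#'
#' Sum over data points of the Student-t log density (\code{nu} degrees
#' of freedom) centred on the model's predicted amplitude with scale
#' \code{n} (scaled by \code{1/sqrt(groupN)} when fitting coherently
#' averaged group data; see \code{\link{groupNoiseScaling}}).
#'
#' @param data data.frame with columns \code{amplitude}, \code{target_c},
#'   \code{mask_c}, \code{role} (\code{"both"} when the two eyes' channel
#'   responses sum into the row's spectral bin, \code{"target"}/
#'   \code{"mask"} for frequency-resolved cross conditions).
#' @param params A \linkS4class{GainControlParams} (Rmax present).
#' @param nu Student-t degrees of freedom (default 5).
#' @param groupN Number of participants behind each averaged data point
#'   (1 for individual data).
#' @return Log likelihood (scalar; \code{-Inf} if the scale is not
#'   positive).
#' @export
loglikAmplitudes <- function(data, params, nu = 5, groupN = 1) {
  stopifnot(is(params, "GainControlParams"))
  if (matchingMode(params))
    stop("amplitude likelihood needs an Rmax parameter")
  terms <- .ampTerms(data)
  .loglikAmpRaw(terms, params@Z, params@w, params@n, params@Rmax,
                nu = nu, groupN = groupN)
}

.loglikAmpRaw <- function(terms, Z, w, n, Rmax, nu = 5, groupN = 1) {
  scale <- n / sqrt(groupN)
  if (!is.finite(scale) || scale <= 0) return(-Inf)
  mu <- .ampPredict(terms, Z, w, n, Rmax)
  sum(dt((terms$y - mu) / scale, df = nu, log = TRUE) - log(scale))
}

#' Bernoulli log likelihood for single-trial matching responses
#'
#' Probability of judging the target more intense is
#' \eqn{\Phi((Resp_{target} - Resp_{standard})/n)} with responses from the
#' matching-mode model (no Rmax).  Probabilities are clipped to
#' \eqn{[10^{-9}, 1 - 10^{-9}]} to keep the log likelihood finite.
#'
#' @param trials data.frame with columns \code{target_cL},
#'   \code{target_cR}, \code{standard_pct}, \code{response} (0/1).
#' @param params A matching-mode \linkS4class{GainControlParams}.
#' @return Log likelihood (scalar).
#' @export
loglikMatching <- function(trials, params) {
  stopifnot(is(params, "GainControlParams"))
  terms <- .matchTerms(trials)
  .loglikMatchRaw(terms, params@Z, params@w, params@n)
}

.matchTerms <- function(trials) {
  need <- c("target_cL", "target_cR", "standard_pct", "response")
  if (!all(need %in% names(trials)))
    stop("matching trials need columns ", paste(need, collapse = ", "))
  list(cL = trials$target_cL, cR = trials$target_cR,
       std = trials$standard_pct, y = trials$response)
}

.loglikMatchRaw <- function(terms, Z, w, n) {
  if (!is.finite(n) || n <= 0) return(-Inf)
  respT <- terms$cL^2 / (Z + terms$cL + w * terms$cR) +
           terms$cR^2 / (Z + terms$cR + w * terms$cL)
  respS <- 2 * terms$std^2 / (Z + terms$std * (1 + w))
  p <- pnorm((respT - respS) / n)
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  sum(terms$y * log(p) + (1 - terms$y) * log1p(-p))
}

#' Group-level noise scaling
#'
#' Coherent averaging across \code{N} participants shrinks the noise by
#' \eqn{\sqrt N}; a model fitted to group-averaged data therefore uses
#' \code{n / sqrt(N)} as its effective noise parameter.
#'
#' @param n Noise parameter.
#' @param N Number of participants averaged (>= 1).
#' @return Scaled noise value.
#' @export
groupNoiseScaling <- function(n, N) {
  if (any(N < 1)) stop("N must be >= 1")
  n / sqrt(N)
}

## ---- diagnostics -------------------------------------------------------

## Split R-hat (each chain halved, between/within variance ratio).
splitRhat <- function(draws) {
  ## draws: iterations x chains matrix
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[seq.int(n - half + 1, n), , drop = FALSE])
  m <- ncol(sub); len <- nrow(sub)
  mu <- colMeans(sub)
  s2 <- apply(sub, 2, var)
  W <- mean(s2)
  B <- len * var(mu)
  if (W == 0) return(1)
  sqrt(((len - 1) / len * W + B / len) / W)
}

## Effective sample size by initial-positive-sequence autocorrelation.
essBasic <- function(draws) {
  n <- nrow(draws); m <- ncol(draws)
  rhoSum <- 0
  for (j in seq_len(m)) {
    x <- draws[, j]
    if (var(x) == 0) next
    a <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    pos <- which(a < 0.05)
    k <- if (length(pos)) pos[1] - 1 else length(a)
    if (k > 0) rhoSum <- rhoSum + sum(a[seq_len(k)])
  }
  rho <- rhoSum / m
  m * n / (1 + 2 * max(rho, 0))
}

## ---- sampler -----------------------------------------------------------

#' Sample the posterior of the gain-control parameters
#'
#' Adaptive random-walk Metropolis on log-transformed parameters
#' (component-wise proposals, step sizes tuned during warmup toward 44\%
#' acceptance).  Amplitude kinds (\code{"pupil"}, \code{"eeg_1f"},
#' \code{"eeg_2f"}) fit (Z, w, n, Rmax) with the Student-t likelihood;
#' \code{"matching"} fits (Z, w, n) with the Bernoulli likelihood (Rmax
#' is omitted: it has no effect in that paradigm).  The reported point
#' estimate is the posterior median; a fit with any split R-hat >= 1.05
#' is returned but flagged as non-converged.
#'
#' @param data Amplitude data.frame (see \code{\link{loglikAmplitudes}})
#'   or matching trials (see \code{\link{loglikMatching}}).
#' @param kind One of \code{"pupil"}, \code{"eeg_1f"}, \code{"eeg_2f"},
#'   \code{"matching"}.
#' @param priors Prior table from \code{\link{priorSpec}}.
#' @param chains Number of chains (default 4).
#' @param draws Post-warmup draws per chain (default 2000).
#' @param warmup Warmup iterations per chain (default 1000).
#' @param seed Integer seed.
#' @param nu Student-t degrees of freedom for amplitude likelihoods.
#' @param groupN Participants behind each averaged amplitude (1 for
#'   individual data).
#' @return A \linkS4class{PosteriorFit}.
#' @examples
#' \donttest{
#' p <- gainParams(Z = 3.44, w = 0.61, n = 0.01, Rmax = 0.00023)
#' d <- generateAmplitudeDataset(ampConfig(params = p, nParticipants = 6,
#'                                         seed = 1))
#' fit <- samplePosterior(participantAmplitudes(d), kind = "pupil",
#'                        chains = 2, draws = 500, warmup = 500, seed = 1)
#' }
#' @export
samplePosterior <- function(data, kind = c("pupil", "eeg_1f", "eeg_2f",
                                           "matching"),
                            priors = priorSpec(), chains = 4,
                            draws = 2000, warmup = 1000, seed = 1,
                            nu = 5, groupN = 1) {
  kind <- match.arg(kind)
  matching <- kind == "matching"
  pnames <- if (matching) c("Z", "w", "n") else c("Z", "w", "n", "Rmax")
  pr <- priors[match(pnames, priors$param), ]
  if (anyNA(pr$mean)) stop("priors must cover ", paste(pnames, collapse = ", "))

  terms <- if (matching) .matchTerms(data) else .ampTerms(data)
  logpost <- if (matching) {
    function(th) { # th on log scale
      x <- exp(th)
      .loglikMatchRaw(terms, x[1], x[2], x[3]) +
        sum(dnorm(x, pr$mean, pr$sd, log = TRUE)) + sum(th)
    }
  } else {
    function(th) {
      x <- exp(th)
      .loglikAmpRaw(terms, x[1], x[2], x[3], x[4], nu = nu,
                    groupN = groupN) +
        sum(dnorm(x, pr$mean, pr$sd, log = TRUE)) + sum(th)
    }
  }

  npar <- length(pnames)
  allDraws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(deriveSeed(seed, ch))
    ## overdispersed start: positive prior draw per parameter
    x0 <- abs(rnorm(npar, pr$mean, pr$sd)) + 1e-6
    th <- log(x0)
    lp <- logpost(th)
    guard <- 0
    while (!is.finite(lp) && guard < 100) {
      th <- log(abs(rnorm(npar, pr$mean, pr$sd)) + 1e-6)
      lp <- logpost(th); guard <- guard + 1
    }
    if (!is.finite(lp))
      stop("could not find a starting point with finite posterior density")
    stepSd <- rep(0.3, npar)
    accWin <- rep(0, npar); nWin <- 0
    keep <- matrix(NA_real_, draws, npar)
    total <- warmup + draws
    for (it in seq_len(total)) {
      for (j in seq_len(npar)) {
        thProp <- th
        thProp[j] <- th[j] + rnorm(1, 0, stepSd[j])
        lpProp <- logpost(thProp)
        if (is.finite(lpProp) && log(runif(1)) < lpProp - lp) {
          th <- thProp; lp <- lpProp
          accWin[j] <- accWin[j] + 1
        }
      }
      nWin <- nWin + 1
      if (it <= warmup && nWin == 25) {
        rate <- accWin / nWin
        stepSd <- stepSd * exp(1.5 * (rate - 0.44))
        stepSd <- pmin(pmax(stepSd, 1e-4), 5)
        accWin[] <- 0; nWin <- 0
      }
      if (it > warmup) keep[it - warmup, ] <- exp(th)
    }
    allDraws[[ch]] <- keep
  }

  summ <- do.call(rbind, lapply(seq_len(npar), function(j) {
    perChain <- vapply(allDraws, function(m) m[, j],
                       numeric(draws))
    pooled <- as.vector(perChain)
    data.frame(param = pnames[j],
               median = median(pooled),
               lower95 = unname(quantile(pooled, 0.025)),
               upper95 = unname(quantile(pooled, 0.975)),
               rhat = splitRhat(perChain),
               ess = essBasic(perChain),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  converged <- all(summ$rhat < 1.05)
  if (!converged)
    warning("non-converged fit: max split R-hat = ",
            format(max(summ$rhat), digits = 4))

  drawsDf <- do.call(rbind, lapply(seq_len(chains), function(ch) {
    m <- as.data.frame(allDraws[[ch]])
    names(m) <- pnames
    cbind(data.frame(chain = ch, draw = seq_len(draws)), m)
  }))
  new("PosteriorFit", draws = drawsDf, summary = summ, kind = kind,
      converged = converged,
      config = list(chains = chains, draws = draws, warmup = warmup,
                    seed = seed, nu = nu, groupN = groupN))
}
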