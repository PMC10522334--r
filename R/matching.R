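## Dichoptic contrast-matching machinery: 1-up/1-down dB staircases, a
## stochastic matching observer driven by the gain-control model, probit
## psychometric fits, and assembly of PSE contours in the (cL, cR) plane.

#' Staircase state
#'
#' 1-up/1-down adaptive staircase moving in logarithmic (dB) contrast
#' steps.  A "target more intense" response moves the level one step down,
#' any other response one step up, so the track converges on the 50\%
#' point of the underlying psychometric function.  The initial 3 dB step
#' is halved after \code{halveAfter} reversals for finer placement; the
#' PSE itself is always re-estimated by maximum likelihood over all
#' trials, so placement only affects efficiency.
#'
#' @slot level current target level, dB re 1\% contrast.
#' @slot step current step size, dB.
#' @slot finalStep step size after halving, dB.
#' @slot halveAfter number of reversals triggering the halving.
#' @slot reversals reversal count so far.
#' @slot lastDir last movement direction (-1, 0, +1).
#' @slot history numeric vector of visited levels.
#'
#' @param startLevel Initial level, dB.
#' @param step Initial step (default 3 dB).
#' @param finalStep Step after halving (default 1.5 dB).
#' @param halveAfter Reversals before halving (default 2).
#' @name Staircase-class
#' @exportClass Staircase
setClass("Staircase",
  representation(level = "numeric", step = "numeric",
                 finalStep = "numeric", halveAfter = "numeric",
                 reversals = "integer", lastDir = "integer",
                 history = "numeric"))

#' @rdname Staircase-class
#' @export
newStaircase <- function(startLevel, step = 3, finalStep = 1.5,
                         halveAfter = 2) {
  new("Staircase", level = startLevel, step = step, finalStep = finalStep,
      halveAfter = halveAfter, reversals = 0L, lastDir = 0L,
      history = startLevel)
}

#' Advance a staircase by one trial
#'
#' @param state A \linkS4class{Staircase}.
#' @param targetMore Logical: did the observer judge the target as more
#'   intense than the standard?
#' @return The updated \linkS4class{Staircase}.
#' @export
staircaseUpdate <- function(state, targetMore) {
  stopifnot(is(state, "Staircase"))
  dir <- if (isTRUE(targetMore)) -1L else 1L
  if (state@lastDir != 0L && dir != state@lastDir) {
    state@reversals <- state@reversals + 1L
    if (state@reversals >= state@halveAfter)
      state@step <- state@finalStep
  }
  state@lastDir <- dir
  state@level <- state@level + dir * state@step
  state@history <- c(state@history, state@level)
  state
}

#' Simulate one matching block
#'
#' Runs a 50-trial 1-up/1-down staircase block for one interocular ratio
#' condition, with responses generated by a stochastic gain-control
#' observer: the probability of judging the target more intense is
#' \eqn{\Phi((Resp_{target} - Resp_{standard}) / n)}, with responses from
#' the matching-mode model (no Rmax; n is the decision-noise SD).  At
#' \code{n = 0} the observer is a deterministic response comparator.
#' Presented contrasts are clipped at 100\%, though the staircase level
#' itself may exceed that.
#'
#' @param observer A matching-mode \linkS4class{GainControlParams}
#'   (Rmax absent; \code{n} is the decision-noise SD).
#' @param ratio Interocular contrast ratio in [0, 1].
#' @param standard Binocular standard contrast, percent (24 or 48 in the
#'   standard design).
#' @param side Which eye carries the higher contrast (\code{"left"} or
#'   \code{"right"}).
#' @param nTrialsBlock Trials per block (default 50).
#' @param seed Optional integer seed.
#' @param startLevel Initial staircase level, dB (default: 6 dB above the
#'   standard).
#' @return data.frame of trials: \code{ratio}, \code{side},
#'   \code{standard_pct}, \code{level_db}, \code{target_cL},
#'   \code{target_cR}, \code{response} (1 = target judged more intense).
#' @export
simulateMatchingBlock <- function(observer, ratio, standard,
                                  side = "left", nTrialsBlock = 50,
                                  seed = NULL, startLevel = NULL) {
  stopifnot(is(observer, "GainControlParams"))
  if (!matchingMode(observer))
    stop("the matching observer must use a matching-mode parameter set")
  if (ratio < 0 || ratio > 1) stop("ratio must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(startLevel)) startLevel <- pctToDb(standard) + 6
  nz <- noiseParam(observer)
  respStd <- binocularResponse(standard, standard, observer)
  st <- newStaircase(startLevel)
  out <- vector("list", nTrialsBlock)
  for (i in seq_len(nTrialsBlock)) {
    cPres <- min(dbToPct(st@level), 100)
    cHi <- cPres; cLo <- ratio * cPres
    respTgt <- binocularResponse(cHi, cLo, observer)
    p <- if (nz > 0) pnorm((respTgt - respStd) / nz) else
      (respTgt > respStd) + 0.5 * (respTgt == respStd)
    resp <- as.integer(runif(1) < p)
    out[[i]] <- data.frame(
      ratio = ratio, side = side, standard_pct = standard,
      level_db = st@level,
      target_cL = if (side == "left") cHi else cLo,
      target_cR = if (side == "left") cLo else cHi,
      response = resp, stringsAsFactors = FALSE)
    st <- staircaseUpdate(st, resp == 1L)
  }
  do.call(rbind, out)
}

#' Fit a cumulative-normal psychometric function
#'
#' Maximum-likelihood probit fit to pooled binary matching responses:
#' \eqn{P(\text{target judged more intense}) = \Phi((x - PSE)/\sigma)}
#' with \eqn{x} the target level in dB.  The PSE is the 50\% point and
#' may legitimately extrapolate beyond 100\% contrast.  Lapse rate is
#' fixed at 0.
#'
#' @param levelsDb Target levels, dB.
#' @param responses Binary responses (1 = target more intense).
#' @return List with \code{pse} (dB), \code{slope} (dB), \code{nTrials},
#'   \code{converged} (FALSE for degenerate or separated data).
#'   Responses that \emph{decrease} with target level fail the
#'   orientation check and raise an error.
#' @export
fitPsychometric <- function(levelsDb, responses) {
  if (length(levelsDb) != length(responses))
    stop("levels and responses must have equal length")
  if (length(responses) < 20)
    stop("need at least 20 trials")
  if (length(unique(levelsDb)) < 3)
    stop("need at least 3 distinct levels")
  if (all(responses == responses[1])) {
    return(list(pse = NA_real_, slope = NA_real_,
                nTrials = length(responses), converged = FALSE))
  }
  fit <- suppressWarnings(
    glm(responses ~ levelsDb, family = binomial(link = "probit")))
  b <- coef(fit)
  if (!all(is.finite(b)) )
    return(list(pse = NA_real_, slope = NA_real_,
                nTrials = length(responses), converged = FALSE))
  if (b[2] < 0)
    stop("orientation check failed: response rate decreases with level ",
         "(are the response labels inverted?)")
  separated <- !fit$converged || b[2] > 1e3
  list(pse = unname(-b[1] / b[2]), slope = unname(1 / b[2]),
       nTrials = length(responses), converged = !separated)
}

#' Assemble a PSE matching contour
#'
#' Converts per-participant psychometric fits into points in the
#' (cL, cR) contrast plane.  PSEs are averaged across participants in dB
#' units; the dominant eye of each condition receives the mean PSE
#' contrast and the other eye that contrast times the condition ratio.
#' Standard errors are radial: they displace each point along the line
#' through the origin.
#'
#' @param fits data.frame with columns \code{participant}, \code{ratio},
#'   \code{side}, \code{pse_db} (one row per participant and condition).
#' @param averageSides If \code{TRUE}, mirror-symmetric left/right
#'   conditions are averaged before conversion.
#' @return data.frame: \code{ratio}, \code{side}, \code{pse_db},
#'   \code{se_db}, \code{cL}, \code{cR}.  Missing conditions produce a
#'   partial contour with a warning.
#' @export
assembleContour <- function(fits, averageSides = FALSE) {
  need <- c("participant", "ratio", "side", "pse_db")
  if (!all(need %in% names(fits)))
    stop("fits must have columns ", paste(need, collapse = ", "))
  if (averageSides) fits$side <- ifelse(fits$ratio == 1, "both", "either")
  key <- unique(fits[c("ratio", "side")])
  expected <- if (averageSides) 5L else 9L
  if (nrow(key) < expected)
    warning("missing condition(s): assembling a partial contour")
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sel <- fits$ratio == key$ratio[i] & fits$side == key$side[i]
    pse <- mean(fits$pse_db[sel], na.rm = TRUE)
    se <- if (sum(sel) > 1) sd(fits$pse_db[sel], na.rm = TRUE) / sqrt(sum(sel))
          else NA_real_
    cHi <- dbToPct(pse); cLo <- key$ratio[i] * cHi
    left <- key$side[i] %in% c("left", "both", "either")
    data.frame(ratio = key$ratio[i], side = key$side[i], pse_db = pse,
               se_db = se,
               cL = if (left) cHi else cLo,
               cR = if (left) cLo else cHi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$ratio, out$side), , drop = FALSE]
}
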