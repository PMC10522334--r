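# Likelihoods against brute-force oracles, the noise-scaling rule, and
# the Metropolis sampler (grid-quadrature cross-check, prior recovery,
# simulation-based calibration, noise-shrinkage consistency).

# hand-written Student-t log density (independent of stats::dt)
tLogDensity <- function(x, mu, scale, nu) {
  z <- (x - mu) / scale
  lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(nu * pi) -
    log(scale) - (nu + 1) / 2 * log1p(z^2 / nu)
}

ampTable <- function(params, design = conditionDesign()) {
  do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    cfg <- design$config[i]; con <- design$contrast[i]
    sc <- stimCondition(cfg, con)
    f <- c(sc@targetFreq, if (!is.na(sc@maskFreq)) sc@maskFreq)
    f <- unique(f)
    do.call(rbind, lapply(f, function(fr) {
      data.frame(config = cfg, contrast = con, freq_hz = fr,
                 role = if (length(f) == 1) "both"
                        else if (fr == sc@targetFreq) "target" else "mask",
                 target_c = con,
                 mask_c = sc@maskContrast,
                 amplitude = Mod(predictedAmplitude(sc, params, fr)),
                 stringsAsFactors = FALSE)
    }))
  }))
}

test_that("amplitude likelihood matches a brute-force t-density oracle", {
  set.seed(61)
  p <- paramsPupil()
  d <- ampTable(p)
  d$amplitude <- d$amplitude + rnorm(nrow(d), 0, 0.005)
  ll <- loglikAmplitudes(d, p, nu = 5)
  # independent oracle: loop over points, recompute the prediction from
  # channelResponse and evaluate the hand-written density
  oracle <- sum(vapply(seq_len(nrow(d)), function(i) {
    both <- d$role[i] == "both"
    mu <- responseScale(p) *
      ((both || d$role[i] == "target") *
         channelResponse(d$target_c[i], d$mask_c[i], p) +
       (both || d$role[i] == "mask") *
         channelResponse(d$mask_c[i], d$target_c[i], p)) + noiseParam(p)
    tLogDensity(d$amplitude[i], mu, noiseParam(p), 5)
  }, numeric(1)))
  expect_equal(ll, oracle, tolerance = 1e-9)
  # noise-free data maximise the likelihood at the generating parameters
  exact <- ampTable(p)
  llTrue <- loglikAmplitudes(exact, p)
  for (Z in c(2, 5)) for (w in c(0.3, 0.9))
    expect_lt(loglikAmplitudes(exact, gainParams(Z, w, 0.01, 0.00023)),
              llTrue)
  # doubling amplitudes and Rmax leaves residuals unchanged except the
  # additive n (scale Rmax-linearity of the numerator)
  half <- exact
  half$amplitude <- 2 * (half$amplitude - 0.01) + 0.01
  p2 <- gainParams(3.44, 0.61, 0.01, 2 * 0.00023)
  expect_equal(loglikAmplitudes(half, p2), llTrue, tolerance = 1e-9)
})

test_that("matching likelihood matches a per-trial oracle", {
  set.seed(62)
  obs <- paramsMatching()
  trials <- generateMatchingDataset(
    matchConfig(obs, standards = 48, ratios = c(0, 0.5, 1),
                repetitions = 1, nTrialsBlock = 40, seed = 63))
  ll <- loglikMatching(trials, obs)
  oracle <- sum(vapply(seq_len(nrow(trials)), function(i) {
    rT <- binocularResponse(trials$target_cL[i], trials$target_cR[i], obs)
    rS <- binocularResponse(trials$standard_pct[i],
                            trials$standard_pct[i], obs)
    pr <- pnorm((rT - rS) / noiseParam(obs))
    pr <- min(max(pr, 1e-9), 1 - 1e-9)
    if (trials$response[i] == 1) log(pr) else log(1 - pr)
  }, numeric(1)))
  expect_equal(ll, oracle, tolerance = 1e-9)
  # equality of target and standard gives p = 1/2 per trial
  eq <- data.frame(target_cL = 48, target_cR = 48, standard_pct = 48,
                   response = 1)
  expect_equal(loglikMatching(eq, obs), log(0.5))
  # vanishing noise drives p to its clipped extreme
  tiny <- gainParams(0.30, 0.09, 1e-12)
  up <- data.frame(target_cL = 60, target_cR = 60, standard_pct = 48,
                   response = 1)
  expect_equal(loglikMatching(up, tiny), log(1 - 1e-9))
})

test_that("group noise scaling is sqrt(N) and invertible", {
  expect_equal(groupNoiseScaling(0.01, 30), 0.01 / sqrt(30),
               tolerance = 1e-12)
  expect_equal(groupNoiseScaling(0.01, 30), 0.001826, tolerance = 1e-3)
  expect_equal(groupNoiseScaling(5, 1), 5)
  expect_equal(groupNoiseScaling(groupNoiseScaling(2, 9) * 3, 1), 2)
  expect_error(groupNoiseScaling(1, 0), ">= 1")
})

test_that("prior draws respect the positivity truncation", {
  pr <- priorSpec()
  expect_setequal(pr$param, c("Z", "w", "n", "Rmax"))
  expect_equal(pr$mean[pr$param == "w"], 1)
  expect_equal(pr$sd[pr$param == "Z"], 2)
  d <- generateAmplitudeDataset(ampConfig(paramsPupil(),
    design = conditionDesign("binocular", c(24, 96)),
    nParticipants = 3, trialsPerCondition = 2, seed = 64))
  # short exploratory chains; convergence is not the subject here
  fit <- suppressWarnings(
    samplePosterior(participantAmplitudes(d), kind = "pupil",
                    chains = 2, draws = 200, warmup = 200, seed = 65))
  expect_true(all(as.matrix(posteriorDraws(fit)[c("Z", "w", "n", "Rmax")])
                  > 0))
})

test_that("posterior medians agree with a dense-grid quadrature oracle", {
  set.seed(66)
  obs <- paramsMatching()
  trials <- generateMatchingDataset(
    matchConfig(obs, standards = 48, ratios = c(0, 0.5, 1),
                repetitions = 1, nTrialsBlock = 50, seed = 67))
  fit <- samplePosterior(trials, kind = "matching", chains = 4,
                         draws = 1500, warmup = 1500, seed = 68)
  s <- posteriorSummary(fit)
  # independent oracle: brute-force quadrature on a dense (Z, w, n) grid
  # spanning the truncated priors' support, marginal medians from the
  # normalised posterior mass
  gZ <- seq(0.005, 12, length.out = 60)
  gw <- seq(0.002, 1.2, length.out = 60)
  gn <- seq(0.5, 14, length.out = 60)
  grid <- expand.grid(Z = gZ, w = gw, n = gn)
  lp <- vapply(seq_len(nrow(grid)), function(i) {
    th <- grid[i, ]
    loglikMatching(trials, gainParams(th$Z, th$w, th$n)) +
      dnorm(th$Z, 5, 2, log = TRUE) + dnorm(th$w, 1, 0.5, log = TRUE) +
      dnorm(th$n, 5, 2, log = TRUE)
  }, numeric(1))
  wgt <- exp(lp - max(lp)); wgt <- wgt / sum(wgt)
  gridMedian <- function(vals) {
    agg <- rowsum(wgt, vals)
    cum <- cumsum(agg[, 1])
    as.numeric(rownames(agg))[which(cum >= 0.5)[1]]
  }
  spacing <- c(Z = gZ[2] - gZ[1], w = gw[2] - gw[1], n = gn[2] - gn[1])
  for (par in c("Z", "w", "n")) {
    gm <- gridMedian(grid[[par]])
    post <- s$median[s$param == par]
    expect_lt(abs(post - gm), 0.05 * max(gm, 0.1) + 2 * spacing[[par]])
  }
})

test_that("uninformative data return the prior for w", {
  set.seed(69)
  # wildly scattered amplitudes: the t-likelihood inflates n and the
  # mean structure becomes irrelevant, so w's posterior ~ its prior
  flat <- data.frame(target_c = rep(c(6, 96), 10),
                     mask_c = 0, role = "both",
                     amplitude = runif(20, 0, 2000))
  fit <- samplePosterior(flat, kind = "pupil", chains = 4, draws = 1500,
                         warmup = 1000, seed = 70)
  wd <- posteriorDraws(fit)$w
  # KS distance against the truncated-normal prior CDF
  pcdf <- function(x) (pnorm((x - 1) / 0.5) - pnorm(-2)) / (1 - pnorm(-2))
  ks <- max(abs(ecdf(wd)(sort(wd)) - pcdf(sort(wd))))
  expect_lt(ks, 0.1)
})

test_that("posterior ranks of the true weight are uniform (SBC)", {
  set.seed(71)
  nrep <- 200
  design <- conditionDesign(c("monocular", "binocular"))
  base <- ampTable(gainParams(1, 1, 1, 1), design)[c("target_c", "mask_c",
                                                     "role")]
  ranks <- integer(nrep)
  nBins <- 10
  L <- 39 # thinned draws per replicate -> rank in 0..39, 10 bins of 4
  for (r in seq_len(nrep)) {
    truth <- c(Z = abs(rnorm(1, 5, 2)), w = abs(rnorm(1, 1, 0.5)),
               n = abs(rnorm(1, 5, 2)), Rmax = abs(rnorm(1, 1, 0.5)))
    gp <- gainParams(truth["Z"], truth["w"], truth["n"], truth["Rmax"])
    mu <- vapply(seq_len(nrow(base)), function(i) {
      both <- base$role[i] == "both"
      responseScale(gp) *
        ((both || base$role[i] == "target") *
           channelResponse(base$target_c[i], base$mask_c[i], gp) +
         (both || base$role[i] == "mask") *
           channelResponse(base$mask_c[i], base$target_c[i], gp)) +
        noiseParam(gp)
    }, numeric(1))
    y <- mu + truth["n"] * rt(length(mu), df = 5)
    d <- cbind(base, amplitude = y)
    fit <- suppressWarnings(
      samplePosterior(d, kind = "pupil", chains = 1, draws = 400,
                      warmup = 300, seed = 7000 + r))
    wd <- posteriorDraws(fit)$w
    thin <- wd[round(seq(1, length(wd), length.out = L))]
    ranks[r] <- sum(thin < truth["w"])
  }
  bins <- table(cut(ranks, breaks = seq(-0.5, L + 0.5,
                                        length.out = nBins + 1)))
  chi <- sum((bins - nrep / nBins)^2 / (nrep / nBins))
  expect_lt(chi, qchisq(0.99, df = nBins - 1))
})

test_that("posterior medians shrink to the truth as noise vanishes", {
  # lower the study's noise parameter itself (trial noise follows it)
  # with participant heterogeneity off, so the only deviation from the
  # model is the noise being reduced
  err <- vapply(c(0.04, 0.01, 0.0025), function(nLevel) {
    p <- gainParams(Z = 3.44, w = 0.61, n = nLevel, Rmax = 0.00023)
    d <- generateAmplitudeDataset(ampConfig(
      p, design = conditionDesign(c("monocular", "binocular")),
      nParticipants = 10, trialsPerCondition = 4, scaleSdLog = 0,
      phaseJitterSd = 0, seed = 72))
    ga <- groupAmplitudes(participantAmplitudes(d), iterations = 100,
                          seed = 73)
    fit <- suppressWarnings(
      samplePosterior(ga, kind = "pupil", chains = 2, draws = 800,
                      warmup = 800, seed = 74, groupN = 10))
    s <- posteriorSummary(fit)
    abs(s$median[s$param == "w"] - 0.61)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})
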