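# Generators: exactness in the noise-free limit, the assumed noise
# structure, determinism under seeds, and design bookkeeping.

test_that("noise-free amplitudes equal the scalar model predictions", {
  p <- paramsPupil()
  d <- generateAmplitudeDataset(ampConfig(p, nParticipants = 2,
    trialsPerCondition = 2, noiseSd = 0, scaleSdLog = 0,
    phaseJitterSd = 0, seed = 81))
  pa <- participantAmplitudes(d, filter = FALSE)
  for (i in seq_len(nrow(pa))) {
    both <- pa$role[i] == "both"
    expected <- responseScale(p) *
      ((both || pa$role[i] == "target") *
         channelResponse(pa$target_c[i], pa$mask_c[i], p) +
       (both || pa$role[i] == "mask") *
         channelResponse(pa$mask_c[i], pa$target_c[i], p)) + noiseParam(p)
    expect_equal(pa$amplitude[i], expected, tolerance = 1e-12)
  }
  # same-frequency binocular rows equal the full binocular response
  bin <- pa[pa$config == "binocular" & pa$participant == 1, ]
  expect_equal(bin$amplitude,
               binocularResponse(bin$contrast, bin$contrast, p),
               tolerance = 1e-12)
})

test_that("a w = 0 generator shows a binocular:monocular ratio of 2", {
  p0 <- gainParams(Z = 3.44, w = 0, n = 0, Rmax = 0.00023)
  d <- generateAmplitudeDataset(ampConfig(p0,
    design = conditionDesign(c("monocular", "binocular")),
    nParticipants = 1, trialsPerCondition = 1, noiseSd = 0,
    scaleSdLog = 0, phaseJitterSd = 0, seed = 82))
  pa <- participantAmplitudes(d, filter = FALSE)
  for (con in c(6, 12, 24, 48, 96)) {
    b <- pa$amplitude[pa$config == "binocular" & pa$contrast == con]
    m <- pa$amplitude[pa$config == "monocular" & pa$contrast == con]
    expect_equal(b / m, 2, tolerance = 1e-12)
  }
})

test_that("trial noise is isotropic in the complex plane", {
  d <- generateAmplitudeDataset(ampConfig(paramsPupil(),
    design = conditionDesign("binocular", 48),
    nParticipants = 1, trialsPerCondition = 1e4, seed = 83))
  expect_equal(nrow(d), 1e4)
  ratio <- var(d$re) / var(d$im)
  expect_gt(ratio, 0.9); expect_lt(ratio, 1.1)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- ampConfig(paramsEeg1F(), design = conditionDesign("dichoptic", 48),
                   nParticipants = 2, trialsPerCondition = 2, seed = 84)
  expect_identical(generateAmplitudeDataset(cfg),
                   generateAmplitudeDataset(cfg))
  rcfg <- rawConfig("pupil", paramsPupil(),
                    design = conditionDesign("monocular", 96),
                    nParticipants = 1, trialsPerCondition = 1, seed = 85)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeTrialsCsv(generateRawTrials(rcfg), f1)
  writeTrialsCsv(generateRawTrials(rcfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  mcfg <- matchConfig(paramsMatching(), standards = 24, ratios = 0.5,
                      repetitions = 1, seed = 86)
  expect_identical(generateMatchingDataset(mcfg),
                   generateMatchingDataset(mcfg))
})

test_that("raw trials recover the injected 2 Hz amplitude", {
  p <- paramsPupil()
  # transient-free, noise-free: pure DFT inversion, recovered exactly
  clean <- rawConfig("pupil", p, design = conditionDesign("binocular", 96),
                     nParticipants = 1, trialsPerCondition = 1,
                     broadbandSd = 0, dropProb = 0, scaleSdLog = 0,
                     onsetAmp = 0, seed = 87)
  rs <- generateRawTrials(clean)
  amp <- analyzeRecordingSet(rs)
  injected <- binocularResponse(96, 96, p)
  got <- sqrt(amp$re^2 + amp$im^2)
  expect_equal(got, rep(injected, length(got)), tolerance = 1e-6)
  # with the onset transient and dropped frames at their defaults the
  # recovery contract is 5%
  dflt <- rawConfig("pupil", p, design = conditionDesign("binocular", 96),
                    nParticipants = 1, trialsPerCondition = 1,
                    broadbandSd = 0, scaleSdLog = 0, seed = 87)
  ampD <- analyzeRecordingSet(generateRawTrials(dflt))
  gotD <- sqrt(ampD$re^2 + ampD$im^2)
  expect_equal(gotD, rep(injected, length(gotD)), tolerance = 0.05)
  # cross-frequency conditions put energy only at the two fundamentals
  # (plus low-frequency leakage from the onset transient)
  crossCfg <- rawConfig("pupil", p,
                        design = conditionDesign("binocular_cross", 48),
                        nParticipants = 1, trialsPerCondition = 1,
                        broadbandSd = 0, dropProb = 0, scaleSdLog = 0,
                        seed = 88)
  sp <- amplitudeSpectrum(epochTrial(trialMatrix(generateRawTrials(crossCfg),
                                                 1)[1, ], 120))
  a <- Mod(amplitudes(sp)); f <- frequencies(sp)
  peaks <- f[a > 0.005 & f > 0.5]
  expect_setequal(peaks, c(1.6, 2))
})

test_that("matching generator covers the full published block design", {
  cfg <- matchConfig(paramsMatching(), seed = 89)
  trials <- generateMatchingDataset(cfg)
  # 54 blocks of 50 trials -> 2700 trials per participant
  expect_equal(nrow(trials), 2700)
  expect_equal(length(unique(trials$block)), 54)
  expect_equal(nrow(unique(trials[c("ratio", "side")])), 9)
  expect_setequal(unique(trials$standard_pct), c(24, 48))
  # per-block trial counts are exactly 50
  expect_true(all(table(trials$block) == 50))
})

test_that("pooled-ratio structure survives the stochastic observer", {
  # a near-linear observer's monocular PSE is about twice its binocular
  # PSE (modest suppression shifts it slightly below 2)
  cfg <- matchConfig(paramsMatching(), standards = 48, seed = 90)
  trials <- generateMatchingDataset(cfg)
  fits <- fitAllConditions(trials)
  ctr <- assembleContour(fits[c("participant", "ratio", "side", "pse_db")])
  mono <- dbToPct(mean(ctr$pse_db[ctr$ratio == 0]))
  bino <- dbToPct(ctr$pse_db[ctr$ratio == 1])
  expect_gt(mono / bino, 1.7)
  expect_lt(mono / bino, 2.0)
  # the binocular match recovers the standard itself
  expect_equal(bino, 48, tolerance = 0.05 * 48)
})
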