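# Gain-control model: scalar equations, waveform mode, matching contours.

test_that("scalar channel and binocular responses match direct arithmetic", {
  p <- paramsPupil()
  expect_equal(channelResponse(48, 48, p), 2304 / 80.72, tolerance = 1e-12)
  pe <- paramsEeg1F()
  expect_equal(channelResponse(96, 0, pe), 9216 / 98.62, tolerance = 1e-12)
  expect_equal(binocularResponse(96, 96, pe),
               0.00336 * 2 * (9216 / 100.54) + 0.15, tolerance = 1e-12)
  # zero own-contrast gives a zero channel response whatever the other eye
  expect_equal(channelResponse(0, 73, p), 0)
  # both eyes dark: only the additive noise term survives
  expect_equal(binocularResponse(0, 0, p), noiseParam(p))
})

test_that("responses are symmetric under eye swap and monotone", {
  p <- gainParams(Z = 2, w = 0.4, n = 0.05, Rmax = 0.01)
  grid <- expand.grid(a = c(0, 3, 17, 48, 96), b = c(0, 6, 29, 96))
  expect_equal(binocularResponse(grid$a, grid$b, p),
               binocularResponse(grid$b, grid$a, p))
  # strictly increasing in own contrast
  cs <- seq(1, 96, length.out = 40)
  r <- channelResponse(cs, 20, p)
  expect_true(all(diff(r) > 0))
  # strictly decreasing in the other eye's contrast when w > 0
  r2 <- channelResponse(48, cs, p)
  expect_true(all(diff(r2) < 0))
  # invariant to the other eye when w = 0
  p0 <- gainParams(Z = 2, w = 0, n = 0.05, Rmax = 0.01)
  expect_equal(channelResponse(48, cs, p0),
               rep(channelResponse(48, 0, p0), length(cs)))
  expect_error(channelResponse(-1, 0, p), "non-negative")
})

test_that("binocular:monocular ratio has the analytic form and bounds", {
  pe <- paramsEeg1F()
  expect_equal(binocularRatio(96, pe), 2 * 98.62 / 100.54,
               tolerance = 1e-12)
  p0 <- gainParams(Z = 3, w = 0, n = 0.1, Rmax = 1)
  for (c in c(2, 48, 96)) expect_equal(binocularRatio(c, p0), 2)
  p1 <- gainParams(Z = 3, w = 1, n = 0.1, Rmax = 1)
  expect_equal(binocularRatio(1e6, p1), 1, tolerance = 1e-3)
  # noise-free ratio lies in (2/(1+w), 2] across contrasts and weights
  for (w in c(0, 0.25, 0.61, 1)) {
    pw <- gainParams(Z = 3.44, w = w, n = 0, Rmax = 1)
    r <- binocularRatio(c(1, 6, 24, 96, 1e4), pw)
    expect_true(all(r > 2 / (1 + w) - 1e-12 & r <= 2 + 1e-12))
  }
  expect_error(binocularRatio(0, p0), "zero contrast")
})

test_that("waveform mode reproduces an independent pointwise evaluation", {
  p <- paramsEeg1F()
  t <- timeBase(500)
  wL <- 96 * sin(2 * pi * 2 * t)
  wR <- 48 * sin(2 * pi * 1.6 * t)
  out <- responseWaveform(wL, wR, 500, p)
  # independent oracle: explicit rectify-then-evaluate loop
  expected <- vapply(seq_along(t), function(i) {
    L <- max(wL[i], 0); R <- max(wR[i], 0)
    0.00336 * (L^2 / (2.62 + L + 0.02 * R) +
               R^2 / (2.62 + R + 0.02 * L)) + 0.15
  }, numeric(1))
  expect_equal(as.numeric(out), expected, tolerance = 1e-12)
  # constant (DC) inputs reproduce scalar mode exactly
  dc <- responseWaveform(rep(48, 100), rep(24, 100), 100, p)
  expect_equal(as.numeric(dc), rep(binocularResponse(48, 24, p), 100))
  # all-dark input: constant n
  dark <- responseWaveform(rep(0, 100), rep(0, 100), 100, p)
  expect_equal(as.numeric(dark), rep(0.15, 100))
  expect_error(responseWaveform(1:10, 1:9, 100, p), "equal length")
})

test_that("single-eye 2 Hz drive concentrates energy at 2 and 4 Hz", {
  p <- paramsEeg1F()
  t <- timeBase(1000)
  y <- responseWaveform(96 * sin(2 * pi * 2 * t), rep(0, length(t)),
                        1000, p)
  sp <- amplitudeSpectrum(y, 1000)
  a <- Mod(amplitudes(sp)); f <- frequencies(sp)
  nonDC <- f > 0.05
  top2 <- f[nonDC][order(a[nonDC], decreasing = TRUE)][1:2]
  expect_setequal(top2, c(2, 4))
})

test_that("intermodulation terms appear iff suppression is non-zero", {
  t <- timeBase(1000)
  wL <- 48 * sin(2 * pi * 2 * t)
  wR <- 48 * sin(2 * pi * 1.6 * t)
  pw <- paramsPupil() # w = 0.61
  sp <- amplitudeSpectrum(responseWaveform(wL, wR, 1000, pw), 1000)
  expect_gt(Mod(binAt(sp, 0.4)), 1e-4)
  expect_gt(Mod(binAt(sp, 3.6)), 1e-4)
  p0 <- gainParams(Z = 3.44, w = 0, n = 0.01, Rmax = 0.00023)
  sp0 <- amplitudeSpectrum(responseWaveform(wL, wR, 1000, p0), 1000)
  fund <- Mod(binAt(sp0, 2))
  expect_lt(Mod(binAt(sp0, 0.4)), 1e-9 * fund)
  expect_lt(Mod(binAt(sp0, 3.6)), 1e-9 * fund)
})

test_that("model matching contour solves the response-match equation", {
  pm <- paramsMatching()
  ctr <- modelMatchingContour(pm, 48)
  # ratio 1 is the standard itself
  expect_equal(ctr$cL[ctr$ratio == 1], 48)
  # independent scalar root-finder oracle for the monocular point
  f <- function(c) binocularResponse(c, 0, pm) -
    binocularResponse(48, 48, pm)
  oracle <- uniroot(f, c(1, 1000), tol = 1e-9)$root
  expect_equal(ctr$cL[ctr$ratio == 0 & ctr$side == "left"], oracle,
               tolerance = 1e-4)
  expect_equal(oracle, 87.9, tolerance = 1e-3)
  # dominant-eye contrast is non-increasing in the ratio
  dom <- ctr$cL[ctr$side == "left"]
  expect_true(all(diff(dom[order(ctr$ratio[ctr$side == "left"])]) <= 0))
  # mirrored points swap eyes
  expect_equal(ctr$cL[ctr$ratio == 0 & ctr$side == "right"], 0)
  # an unreachable standard errors rather than returning garbage
  expect_error(
    modelMatchingContour(gainParams(Z = 1e6, w = 0, n = 5), 96,
                         ratios = 0, ceiling = 1),
    "unreachable")
})

test_that("canonical contours follow their defining loci", {
  lin <- canonicalContour("linear", 48)
  expect_equal(lin$cL + lin$cR, rep(96, nrow(lin)))
  expect_equal(lin$cL[lin$ratio == 0 & lin$side == "left"], 96)
  lin24 <- canonicalContour("linear", 24)
  expect_equal(lin24$cL[lin24$ratio == 1], 24)
  wta <- canonicalContour("max", 48)
  expect_equal(pmax(wta$cL, wta$cR), rep(48, nrow(wta)))
  expect_error(canonicalContour("mean", 48), "arg")
})

test_that("parameter validity is enforced", {
  expect_error(gainParams(Z = -1, w = 0.5, n = 0.1), "Z must be")
  expect_error(gainParams(Z = 1, w = -0.1, n = 0.1), "w must be")
  expect_error(gainParams(Z = 1, w = 0.5, n = 0.1, Rmax = 0), "Rmax")
  expect_error(new("GainControlParams", Z = 1, w = 0, n = 0,
                   Rmax = NA_real_, p = 3), "fixed at 2")
  p <- gainParams(Z = 1, w = 0.5, n = 0.1)
  expect_true(matchingMode(p))
  expect_false(matchingMode(paramsPupil()))
})

test_that("stimulus conditions validate and predict scalar amplitudes", {
  sc <- stimCondition("dichoptic", 24)
  expect_equal(ocularConfig(sc), "dichoptic")
  p <- paramsPupil()
  expect_equal(predictedAmplitude(sc, p),
               binocularResponse(24, 48, p))
  scm <- stimCondition("monocular", 96)
  expect_equal(predictedAmplitude(scm, p), binocularResponse(96, 0, p))
  expect_error(stimCondition("dichoptic", 24, maskContrast = 30),
               "48")
  expect_error(stimCondition("monocular", 150), "0, 100")
  expect_error(stimCondition("sideways", 24), "unknown")
})
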