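# Synthetic embryo generator: nuclear-level model, rendering invariants,
# noise operator, FRAP and fixed-image ground truth.

test_that("nuclear level model reproduces the piecewise closed form", {
  # identity without perturbation
  p0 <- perturbation("none")
  expect_equal(nuclearLevelModel(c(0, 3, 12), p0, 100), rep(100, 3))

  # export: instantaneous decay limit reaches the 10% floor; recovery is the
  # stated exponential with I_ss = baseline
  pe <- perturbation("export", lightOnFrame = 1, lightOffFrame = 25,
                     exportRate = 1e9, reimportRate = 0.5)
  tOff <- 24 * 25 / 60
  expect_equal(nuclearLevelModel(tOff - 1e-6, pe, 100), 10, tolerance = 1e-6)
  expect_equal(nuclearLevelModel(tOff + 1 / 0.5, pe, 100),
               100 - 90 * exp(-1), tolerance = 1e-9)

  # zero-rate degradation is constant
  pd <- perturbation("degrade", lightOnFrame = 2, lightOffFrame = 10,
                     degradeRate = 0)
  expect_equal(nuclearLevelModel(seq(0, 10, by = 1), pd, 50), rep(50, 11))

  # degradation continues for the post-light delay, then holds
  pd2 <- perturbation("degrade", lightOnFrame = 1, lightOffFrame = 5,
                      degradeRate = 0.3, degradePostLightDelay = 2)
  dt <- 25 / 60
  tEnd <- (4 + 2) * dt
  lateLevel <- 100 * exp(-0.3 * tEnd)
  expect_equal(nuclearLevelModel(tEnd + 5, pd2, 100), lateLevel)
  expect_lt(nuclearLevelModel(tEnd - 1e-6, pd2, 100) - lateLevel, 1e-3)

  expect_error(nuclearLevelModel(-1, p0, 100), "non-negative")
})

test_that("movies are byte-identical under a fixed seed", {
  cfg <- flatFieldConfig(nFrames = 3L,
                         noise = list(gaussianSd = 30, poisson = TRUE,
                                      saltPepperFraction = 0.001))
  a <- simulateNucleiMovie(cfg)
  b <- simulateNucleiMovie(cfg)
  expect_identical(stackData(a$stack), stackData(b$stack))
  expect_identical(a$truth, b$truth)

  cfgF <- defaultFociConfig(nFrames = 2L)
  fa <- simulateFociMovie(cfgF)
  fb <- simulateFociMovie(cfgF)
  expect_identical(stackData(fa$stack), stackData(fb$stack))
  expect_identical(fa$truth$fociTruth, fb$truth$fociTruth)
})

test_that("unperturbed movies hold nuclear intensity constant to quantization", {
  cfg <- flatFieldConfig(nFrames = 3L)
  sim <- simulateNucleiMovie(cfg)
  tr <- sim$truth$nucleiTracks
  for (i in unique(tr$track)) {
    pos <- tr[tr$track == i & tr$frame == 1, ]
    vals <- vapply(1:3, function(t) {
      img <- stackFrame(sim$stack, t)
      p <- optoquant:::.softDiskPatch(pos$y, pos$x,
                                      sim$truth$radiusPx * 0.6, dim(img))
      mean(img[p$y, p$x][p$w > 0.9])
    }, numeric(1))
    expect_lte(max(vals) - min(vals), 1 + 1e-9)
  }
})

test_that("export conserves total embryo signal and drains nuclei to the floor", {
  cfg <- flatFieldConfig(
    nFrames = 40L, seed = 11L,
    perturbation = perturbation("export", lightOnFrame = 10,
                                lightOffFrame = 34, exportRate = 3,
                                reimportRate = 0.24))
  sim <- simulateNucleiMovie(cfg)
  mask <- sim$truth$embryoMask
  totals <- vapply(1:40, function(t) sum(stackFrame(sim$stack, t)[mask]),
                   numeric(1))
  expect_lt(diff(range(totals[10:34])) / totals[10], 0.02)

  # at light-off (10 min at 3/min) nuclei have reached the floor: < 15% of
  # the pre-light in-nucleus mean
  lev <- sim$truth$nuclearLevel
  expect_lt(mean(lev[, 34]) / mean(lev[, 1]), 0.15)
})

test_that("degradation decays monotonically with no recovery", {
  cfg <- flatFieldConfig(
    nFrames = 40L, seed = 12L,
    perturbation = perturbation("degrade", lightOnFrame = 10,
                                lightOffFrame = 30, degradeRate = 0.5,
                                degradePostLightDelay = 2))
  sim <- simulateNucleiMovie(cfg)
  mask <- sim$truth$embryoMask
  means <- vapply(1:40, function(t) mean(stackFrame(sim$stack, t)[mask]),
                  numeric(1))
  expect_true(all(diff(means[10:30]) <= 1e-9))
  # still decreasing through the post-light delay, flat afterwards
  expect_lt(means[32], means[30])
  expect_equal(means[35], means[40], tolerance = 1e-6)
})

test_that("focus ground truth respects domain, mask and activation rules", {
  cfg <- defaultFociConfig(nFrames = 3L)
  cfg@foci$activationProb <- 1
  sim <- simulateFociMovie(cfg)
  tru <- sim$truth$fociTruth
  # saturated activation: every in-domain nucleus has one spot, every frame
  expect_equal(unname(tabulate(tru$frame, 3)),
               rep(sum(sim$truth$inDomain), 3))
  # every spot centroid inside the embryo mask and inside its nucleus disk
  expect_true(all(sim$truth$embryoMask[cbind(round(tru$y), round(tru$x))]))
  expect_error(simulateFociMovie({
    c2 <- cfg; c2@foci$domain <- list(c(2, 3)); c2
  }), "no nuclei")
})

test_that("export-mode spots switch off during light and recover after", {
  cfg <- defaultFociConfig(
    nFrames = 80L,
    perturbation = perturbation("export", lightOnFrame = 20,
                                lightOffFrame = 44, exportRate = 3,
                                reimportRate = 0.24))
  sim <- simulateFociMovie(cfg)
  counts <- tabulate(sim$truth$fociTruth$frame, 80)
  expect_gt(counts[1], 0)
  expect_equal(min(counts[20:44]), 0)
  expect_equal(counts[80], counts[1])

  cfgD <- defaultFociConfig(
    nFrames = 80L,
    perturbation = perturbation("degrade", lightOnFrame = 20,
                                lightOffFrame = 44, degradeRate = 0.3))
  simD <- simulateFociMovie(cfgD)
  countsD <- tabulate(simD$truth$fociTruth$frame, 80)
  expect_equal(countsD[80], 0)   # no recovery once degraded
})

test_that("FRAP rendering matches the closed-form recovery", {
  cfg <- frapConfig(nFrames = 60L, seed = 6L)
  sim <- simulateFrapMovie(cfg, c(96, 96, 40), 21:40,
                           c(Iss = 8628, alpha = 7807, beta = 0.23))
  b1 <- sim$truth$bleached[1]
  pos <- sim$truth$positions[b1, ]
  img40 <- stackFrame(sim$stack, 40)
  p <- optoquant:::.softDiskPatch(pos[1], pos[2], sim$truth$radiusPx * 0.7,
                                  dim(img40))
  # bleach end: I_ss - alpha = 821 a.u. before noise
  expect_equal(mean(img40[p$y, p$x][p$w > 0.9]), 8628 - 7807, tolerance = 0.01)
  # sampled trace follows I(t) = I_ss - alpha exp(-beta t) after bleaching
  tMin <- sim$truth$timeMin
  for (t in c(45, 52, 60)) {
    img <- stackFrame(sim$stack, t)
    expected <- 8628 - 7807 * exp(-0.23 * (tMin[t] - tMin[40]))
    expect_equal(mean(img[p$y, p$x][p$w > 0.9]), expected, tolerance = 2)
  }
  # alpha = 0 leaves the trace flat
  simFlat <- simulateFrapMovie(frapConfig(nFrames = 50L, seed = 6L),
                               c(96, 96, 40), 21:40,
                               c(Iss = 5000, alpha = 1e-9, beta = 0.23))
  lev <- simFlat$truth$nuclearLevel[simFlat$truth$bleached[1], ]
  expect_lt(diff(range(lev)), 1e-3)
})

test_that("noise operator is the identity at zero and binomial for salt-pepper", {
  s <- imageStack(array(100, c(512, 512, 1)), 0.29, 25)
  n0 <- applyNoise(s, list(gaussianSd = 0, poisson = FALSE,
                           saltPepperFraction = 0))
  expect_identical(stackData(n0), stackData(s))

  # fraction 0.001 on 512 x 512: pepper count ~ Binomial(262144, 0.0005)
  n1 <- applyNoise(s, list(gaussianSd = 0, poisson = FALSE,
                           saltPepperFraction = 0.001), seed = 1)
  nPepper <- sum(stackData(n1) == 0)
  expect_gt(nPepper, 131 - 35)
  expect_lt(nPepper, 131 + 35)
  # with a distinct maximum, salt + pepper together ~ 262 +/- 35
  d <- array(100, c(512, 512, 1)); d[1] <- 60000
  s2 <- imageStack(d, 0.29, 25)
  n2 <- applyNoise(s2, list(gaussianSd = 0, poisson = FALSE,
                            saltPepperFraction = 0.001), seed = 2)
  nRep <- sum(stackData(n2) == 0) + sum(stackData(n2) == 60000) - 1
  expect_gt(nRep, 262 - 35)
  expect_lt(nRep, 262 + 35)

  n1b <- applyNoise(s, list(gaussianSd = 0, poisson = FALSE,
                            saltPepperFraction = 0.001), seed = 1)
  expect_identical(stackData(n1), stackData(n1b))
})

test_that("fixed embryo ground truth encodes widths and gradient", {
  cfg <- simConfig(view = "cross-section-profile", imageShape = c(256, 256),
                   nFrames = 1, seed = 7)
  # full-circumference domain has width exactly 1
  fxFull <- simulateFixedEmbryo(cfg, channels = list(
    list(name = "all", intervals = list(c(0, 1)))))
  expect_equal(unlist(fxFull$truth$trueWidths$all), 1, tolerance = 1e-9)
  # ... and the rendered channel covers the whole ring band
  expect_true(all(fxFull$channels$expression$all[
    abs(optoquant:::.ellipticCoords(c(256, 256),
                                    fxFull$truth$midEllipse)$rho - 1) < 0.05
  ] > 0))

  # flat gradient: nuclear levels uniform along DV
  cfgFlat <- simConfig(view = "cross-section-profile",
                       imageShape = c(256, 256), nFrames = 1, seed = 7,
                       gradient = list(amplitude = 0, peakPosition = 0,
                                       sigma = 0.14, offset = 300))
  fxFlat <- simulateFixedEmbryo(cfgFlat)
  expect_lt(diff(range(fxFlat$truth$nucleusLevels)), 1e-9)
  expect_error(simulateFixedEmbryo(cfg, channels = rep(list(
    list(name = "x", intervals = list(c(0, 0.1)))), 4)), "at most 3")
})

test_that("a circle-embryo 90-degree sector has true width 0.25", {
  # square field makes the embryo ellipse a circle up to the a/b presets
  cfg <- simConfig(view = "cross-section-profile", imageShape = c(256, 256),
                   nFrames = 1, seed = 7)
  fx <- simulateFixedEmbryo(cfg, channels = list(
    list(name = "q", intervals = list(c(0, 0.25)))))
  mid <- fx$truth$midEllipse
  circ <- list(cy = mid$cy, cx = mid$cx, a = mid$a, b = mid$a, theta = 0)
  w <- ellipseArcLength(circ, 0, pi / 2) / ellipsePerimeter(circ)
  expect_equal(w, 0.25, tolerance = 1e-9)
})
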