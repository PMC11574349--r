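# Nucleus segmentation, embryo ellipse, midline band, intensity traces and
# track linking.

test_that("segmentation recovers every nucleus on a sparse flat field", {
  cfg <- flatFieldConfig(nucleusSpacingUm = 10)
  sim <- simulateNucleiMovie(cfg)
  seg <- segmentNucleiFrame(stackFrame(sim$stack, 1), segParams())
  tr <- sim$truth$nucleiTracks[sim$truth$nucleiTracks$frame == 1, ]
  expect_equal(nrow(seg$objects), nrow(tr))
  d <- vapply(seq_len(nrow(tr)), function(i)
    min(sqrt((seg$objects$y - tr$y[i])^2 + (seg$objects$x - tr$x[i])^2)),
    numeric(1))
  expect_lt(max(d), 1)
  expect_false(seg$carriedForward)
})

test_that("dense nc14-like fields are segmented to within ~1.5 px", {
  cfg <- flatFieldConfig()   # 8 um spacing, embryo edge in frame
  sim <- simulateNucleiMovie(cfg)
  seg <- segmentNucleiFrame(stackFrame(sim$stack, 1), segParams())
  tr <- sim$truth$nucleiTracks[sim$truth$nucleiTracks$frame == 1, ]
  expect_equal(nrow(seg$objects), nrow(tr))
  d <- vapply(seq_len(nrow(tr)), function(i)
    min(sqrt((seg$objects$y - tr$y[i])^2 + (seg$objects$x - tr$x[i])^2)),
    numeric(1))
  expect_lt(max(d), 2)
})

test_that("watershed separates touching nuclei", {
  img <- matrix(0, 64, 64)
  for (cc in list(c(32, 23), c(32, 41))) {   # tangent at one point
    p <- optoquant:::.softDiskPatch(cc[1], cc[2], 9, c(64, 64))
    img[p$y, p$x] <- img[p$y, p$x] + 500 * p$w
  }
  seg <- segmentNucleiFrame(img, segParams())
  expect_equal(nrow(seg$objects), 2)
  # each true disk covered mostly by one label
  lab <- seg$labelImage
  for (cc in list(c(32, 23), c(32, 41))) {
    p <- optoquant:::.softDiskPatch(cc[1], cc[2], 6, c(64, 64))
    inner <- lab[p$y, p$x][p$w > 0.9]
    expect_gte(max(table(inner[inner > 0])) / sum(inner > 0), 0.9)
  }
})

test_that("carry-forward reuses the previous labels on blank frames", {
  cfg <- flatFieldConfig(nFrames = 1L)
  sim <- simulateNucleiMovie(cfg)
  good <- segmentNucleiFrame(stackFrame(sim$stack, 1), segParams())
  blank <- matrix(500, 192, 192)
  cf <- segmentNucleiFrame(blank, segParams(), prev = good)
  expect_true(cf$carriedForward)
  expect_identical(cf$labelImage, good$labelImage)
  expect_equal(nrow(cf$objects), nrow(good$objects))
  # intensities re-measured on the (uniform) current frame
  expect_equal(unique(round(cf$objects$meanIntensity)), 500)
  # carry-forward never changes the count across consecutive blank frames
  cf2 <- segmentNucleiFrame(blank, segParams(), prev = cf)
  expect_equal(nrow(cf2$objects), nrow(cf$objects))
  expect_error(segmentNucleiFrame(blank, segParams(), prev = NULL),
               "no nuclei")
})

test_that("embryo ellipse is recovered from the thresholded boundary", {
  # geometry at the population-view scale: a = 400, b = 200 px
  cfg <- simConfig(imageShape = c(500L, 870L), nFrames = 1, seed = 4,
                   gradient = list(amplitude = 0, peakPosition = 0.5,
                                   sigma = 0.25, offset = 500))
  sim <- simulateNucleiMovie(cfg)
  tru <- sim$truth$embryoEllipse
  ell <- fitEmbryoEllipse(sim$stack, segParams())
  expect_equal(ell$a / tru$a, 1, tolerance = 0.02)
  expect_equal(ell$b / tru$b, 1, tolerance = 0.02)
  expect_lt(abs(ell$theta - tru$theta) * 180 / pi, 2)

  # circular embryo: a and b agree within 1%
  cfgC <- simConfig(imageShape = c(420L, 420L), nFrames = 1, seed = 4,
                    gradient = list(amplitude = 0, peakPosition = 0.5,
                                    sigma = 0.25, offset = 500))
  simC <- simulateNucleiMovie(cfgC)
  # force a circle by overriding the preset aspect: draw from truth mask
  ellC <- fitEmbryoEllipse(simC$stack, segParams())
  expect_equal(ellC$a / ellC$b, simC$truth$embryoEllipse$a /
                 simC$truth$embryoEllipse$b, tolerance = 0.01)

  dark <- imageStack(array(0, c(64, 64, 2)), 0.29, 25)
  expect_error(fitEmbryoEllipse(dark, segParams()), "dark")
})

test_that("midline band keeps nuclei within 100 px inclusively", {
  ell <- list(cy = 100, cx = 100, a = 300, b = 150, theta = 0)
  obj <- data.frame(label = 1:4, y = c(100, 200, 201, 0.5), x = rep(100, 4))
  kept <- midlineBandFilter(obj, ell, bandPx = 100)
  expect_true(all(c(1, 2) %in% kept$label))   # on midline; at exactly 100 px
  expect_false(3 %in% kept$label)             # at 101 px
  expect_true(4 %in% kept$label)

  # analytic count on a synthetic field
  cfg <- flatFieldConfig(nFrames = 1L)
  sim <- simulateNucleiMovie(cfg)
  tr <- sim$truth$nucleiTracks[sim$truth$nucleiTracks$frame == 1, ]
  tru <- sim$truth$embryoEllipse
  band <- 40
  expected <- sum(abs(tr$y - tru$cy) <= band)
  seg <- segmentNucleiFrame(stackFrame(sim$stack, 1), segParams())
  kept2 <- midlineBandFilter(seg$objects, tru, bandPx = band)
  expect_equal(nrow(kept2), expected)
})

test_that("mean trace follows the nuclear-level model", {
  cfg <- flatFieldConfig(
    nFrames = 50L, seed = 9L,
    perturbation = perturbation("export", lightOnFrame = 10,
                                lightOffFrame = 34, exportRate = 3,
                                reimportRate = 0.24),
    noise = list(gaussianSd = 2, poisson = FALSE, saltPepperFraction = 0))
  sim <- simulateNucleiMovie(cfg)
  segs <- segmentNuclei(sim$stack, segParams())
  tsr <- intensityTimeseries(segs, 25)
  model <- nuclearLevelModel(tsr$timeMin, cfg@perturbation, 500, 25)
  expect_lt(max(abs(tsr$mean - model) / 500), 0.05)
  # permutation invariance of the mean +/- sd trace
  segsPerm <- segs
  o <- segsPerm[[1]]$objects
  segsPerm[[1]]$objects <- o[sample(nrow(o)), ]
  tsrPerm <- intensityTimeseries(segsPerm, 25)
  expect_equal(tsrPerm$mean, tsr$mean)
  expect_equal(tsrPerm$sd, tsr$sd)
})

test_that("degrade-mode trace keeps falling through the post-light delay", {
  cfg <- flatFieldConfig(
    nFrames = 40L, seed = 12L,
    perturbation = perturbation("degrade", lightOnFrame = 10,
                                lightOffFrame = 30, degradeRate = 0.5,
                                degradePostLightDelay = 2))
  sim <- simulateNucleiMovie(cfg)
  segs <- segmentNuclei(sim$stack, segParams())
  tsr <- intensityTimeseries(segs, 25)
  expect_lt(tsr$mean[32], tsr$mean[30])
  expect_equal(tsr$mean[33], tsr$mean[40], tolerance = 0.01)
})

test_that("static nuclei produce pure gap-free tracks", {
  cfg <- flatFieldConfig(nFrames = 25L)
  sim <- simulateNucleiMovie(cfg)
  segs <- segmentNuclei(sim$stack, segParams())
  ts <- linkTracks(segs)
  nTrue <- length(unique(sim$truth$nucleiTracks$track))
  expect_equal(length(trackIds(ts)), nTrue)
  expect_equal(nrow(trackGaps(ts)), 0)
  expect_true(all(trackPurity(ts, sim$truth$nucleiTracks) == 1))
  # one-to-one: no frame appears twice within a track
  tab <- trackTable(ts)
  expect_false(any(duplicated(tab[, c("track", "frame")])))
})

test_that("drifting nuclei with an occlusion are bridged as one gap", {
  cfg <- flatFieldConfig(nFrames = 100L, seed = 8L,
                         driftPxPerFrame = c(0.08, 0.12),
                         occlusions = list(list(nucleus = 5, frames = 45:49)))
  sim <- simulateNucleiMovie(cfg)
  segs <- segmentNuclei(sim$stack, segParams())
  ts <- linkTracks(segs)
  expect_true(all(trackPurity(ts, sim$truth$nucleiTracks) == 1))
  g <- trackGaps(ts)
  expect_equal(nrow(g), 1)
  expect_equal(g$to - g$from + 1L, 5L)
  expect_lte(g$to - g$from + 1L, 10L)
})

test_that("track filters drop late-appearing tracks", {
  # synthetic segmentations: object A present all 100 frames, object B only
  # in the last 30 -> B removed by the < half rule and first-10 rule
  mkSeg <- function(objs) list(labelImage = matrix(0L, 4, 4), objects = objs)
  segs <- lapply(1:100, function(f) {
    o <- data.frame(label = 1L, y = 10, x = 10, area = 50, meanIntensity = 1)
    if (f > 70)
      o <- rbind(o, data.frame(label = 2L, y = 40, x = 40, area = 50,
                               meanIntensity = 1))
    mkSeg(o)
  })
  ts <- linkTracks(segs, radius = 5)
  expect_equal(length(trackIds(ts)), 1)
  expect_equal(nrow(trackTable(ts)), 100)
})
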