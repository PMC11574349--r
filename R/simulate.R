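# Synthetic embryo generator: nuclei movies, MS2 foci movies, FRAP movies and
# fixed cross-section images, all with full ground truth. The generator is the
# test bed for every downstream quantification stage.

#' Optogenetic perturbation specification
#'
#' Describes how nuclear levels respond to a blue-light window. `"export"`
#' drives nuclear levels down toward a floor during light and recovers them
#' after light-off as I(t) = I_ss - alpha * exp(-beta * t); `"degrade"` decays
#' both compartments during light, keeps decaying for a short delay after
#' light-off, and never recovers.
#'
#' @param mode "none", "export" or "degrade".
#' @param lightOnFrame,lightOffFrame 1-based frame indices delimiting the
#'   light window (light is on for frames in [lightOnFrame, lightOffFrame)).
#' @param exportRate nuclear export rate during light (1/min).
#' @param reimportRate re-import (recovery) rate after light-off (1/min);
#'   this is the beta of the recovery exponential.
#' @param degradeRate degradation rate during light (1/min).
#' @param degradePostLightDelay frames of continued degradation after
#'   light-off (degradation machinery switches off with a slight delay).
#' @param exportFloorFraction fraction of baseline that nuclear levels decay
#'   toward during export (nuclear signal never quite reaches zero).
#' @return A named list used as the `perturbation` slot of a [SimConfig-class].
#' @export
perturbation <- function(mode = c("none", "export", "degrade"),
                         lightOnFrame = 1L, lightOffFrame = 2L,
                         exportRate = 3, reimportRate = 0.24,
                         degradeRate = 0.3, degradePostLightDelay = 2L,
                         exportFloorFraction = 0.1) {
  mode <- match.arg(mode)
  list(mode = mode,
       lightOnFrame = as.integer(lightOnFrame),
       lightOffFrame = as.integer(lightOffFrame),
       exportRate = exportRate, reimportRate = reimportRate,
       degradeRate = degradeRate,
       degradePostLightDelay = as.integer(degradePostLightDelay),
       exportFloorFraction = exportFloorFraction)
}

#' Build a simulation configuration
#'
#' Defaults mirror the population-view live acquisition: 512 x 512 px frames,
#' 0.29 um/px, one frame per 25 s, nc14-scale nuclei on a jittered hexagonal
#' lattice, and a dorsal-ventral Gaussian gradient of nuclear levels.
#'
#' @param view viewing geometry; "ventral" and "dorsolateral" are live views,
#'   "cross-section-profile" is the fixed-image geometry.
#' @param imageShape c(Y, X) in px.
#' @param pixelSizeUm,frameIntervalS,nFrames acquisition parameters.
#' @param nucleusRadiusUm,nucleusSpacingUm nuclear geometry (um).
#' @param gradient list(amplitude, peakPosition, sigma, offset); positions and
#'   sigma are fractions of the DV coordinate, amplitudes in a.u.
#' @param perturbation see [perturbation()].
#' @param foci list(spotSigmaUm, spotAmplitude, domain, activationProb,
#'   deactivationThreshold, deactivationDelayFrames). `domain` is a list of DV
#'   intervals (fractions); see [snaDomain()] and [sogDomain()].
#' @param noise list(gaussianSd, poisson, saltPepperFraction).
#' @param driftPxPerFrame c(dy, dx) rigid drift of the nuclear field per frame.
#' @param occlusions list of list(nucleus =, frames =) scripted invisibility.
#' @param seed integer RNG seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(imageShape = c(64, 64), nFrames = 3, seed = 1)
#' @export
simConfig <- function(view = "ventral",
                      imageShape = c(512L, 512L),
                      pixelSizeUm = 0.29,
                      frameIntervalS = 25,
                      nFrames = 50L,
                      nucleusRadiusUm = 2.6,
                      nucleusSpacingUm = 7.2,
                      gradient = list(amplitude = 600, peakPosition = 0.5,
                                      sigma = 0.18, offset = 200),
                      perturbation = optoquant::perturbation("none"),
                      foci = list(spotSigmaUm = 0.35, spotAmplitude = 2000,
                                  domain = snaDomain(),
                                  activationProb = 0.9,
                                  deactivationThreshold = 0.5,
                                  deactivationDelayFrames = 2L),
                      noise = list(gaussianSd = 0, poisson = FALSE,
                                   saltPepperFraction = 0),
                      driftPxPerFrame = c(0, 0),
                      occlusions = list(),
                      seed = 0L) {
  new("SimConfig", view = view, imageShape = as.integer(imageShape),
      pixelSizeUm = pixelSizeUm, frameIntervalS = frameIntervalS,
      nFrames = as.integer(nFrames), nucleusRadiusUm = nucleusRadiusUm,
      nucleusSpacingUm = nucleusSpacingUm, gradient = gradient,
      perturbation = perturbation, foci = foci, noise = noise,
      driftPxPerFrame = driftPxPerFrame, occlusions = occlusions,
      seed = as.integer(seed))
}

#' @rdname simConfig
#' @param ... overrides passed on to [simConfig()].
#' @details `frapConfig()` switches to the high-zoom FRAP regime:
#'   0.100 um/px and one frame per 2 s.
#' @export
frapConfig <- function(imageShape = c(192L, 192L), pixelSizeUm = 0.100,
                       frameIntervalS = 2, nFrames = 120L,
                       nucleusRadiusUm = 2.4, nucleusSpacingUm = 6.0, ...) {
  simConfig(imageShape = imageShape, pixelSizeUm = pixelSizeUm,
            frameIntervalS = frameIntervalS, nFrames = nFrames,
            nucleusRadiusUm = nucleusRadiusUm,
            nucleusSpacingUm = nucleusSpacingUm, ...)
}

#' Expression-domain presets
#'
#' DV intervals (fractions of the DV coordinate, ventral midline at 0.5 in the
#' ventral view) occupied by the high-threshold ventral domain (`snaDomain`)
#' or the two low-threshold lateral stripes (`sogDomain`).
#' @param center,halfWidth centre and half-width of the ventral band.
#' @export
snaDomain <- function(center = 0.5, halfWidth = 0.16)
  list(c(center - halfWidth, center + halfWidth))

#' @rdname snaDomain
#' @param centers stripe centres; @param stripeHalfWidth stripe half-width.
#' @export
sogDomain <- function(centers = c(0.22, 0.78), stripeHalfWidth = 0.07)
  lapply(centers, function(ct) c(ct - stripeHalfWidth, ct + stripeHalfWidth))

#' Piecewise nuclear-level model under optogenetic perturbation
#'
#' Closed-form nuclear intensity at time `tMin` (minutes from frame 1) for a
#' given perturbation. Export decays exponentially toward a floor during
#' light and recovers after light-off as I_ss - alpha * exp(-beta * t') with
#' I_ss equal to the pre-light baseline; degradation decays during light and
#' for `degradePostLightDelay` frames afterwards, then holds with no
#' recovery. The curve is continuous at every segment boundary.
#'
#' @param tMin time(s) in minutes, >= 0.
#' @param spec a [perturbation()] list.
#' @param baseline pre-light nuclear level (a.u., > 0).
#' @param frameIntervalS frame interval used to convert the frame indices in
#'   `spec` to minutes.
#' @return Nuclear level(s), same length as `tMin`.
#' @export
nuclearLevelModel <- function(tMin, spec, baseline, frameIntervalS = 25) {
  if (any(tMin < 0)) stop("time must be non-negative")
  if (baseline <= 0) stop("baseline must be > 0")
  if (spec$mode == "none") return(rep(baseline, length(tMin)))
  dtMin <- frameIntervalS / 60
  tOn <- (spec$lightOnFrame - 1L) * dtMin
  tOff <- (spec$lightOffFrame - 1L) * dtMin
  out <- numeric(length(tMin))
  if (spec$mode == "export") {
    fl <- spec$exportFloorFraction * baseline
    levOff <- fl + (baseline - fl) * exp(-spec$exportRate * (tOff - tOn))
    alpha <- baseline - levOff
    pre <- tMin < tOn
    dur <- tMin >= tOn & tMin < tOff
    post <- tMin >= tOff
    out[pre] <- baseline
    out[dur] <- fl + (baseline - fl) * exp(-spec$exportRate * (tMin[dur] - tOn))
    out[post] <- baseline - alpha * exp(-spec$reimportRate * (tMin[post] - tOff))
  } else {
    tEnd <- tOff + spec$degradePostLightDelay * dtMin
    pre <- tMin < tOn
    dur <- tMin >= tOn & tMin < tEnd
    post <- tMin >= tEnd
    out[pre] <- baseline
    out[dur] <- baseline * exp(-spec$degradeRate * (tMin[dur] - tOn))
    out[post] <- baseline * exp(-spec$degradeRate * (tEnd - tOn))
  }
  out
}

# ---- internal geometry helpers ----------------------------------------------

# Embryo ellipse for live views: AP axis horizontal, centred in the field.
.embryoEllipse <- function(config) {
  Y <- config@imageShape[1]; X <- config@imageShape[2]
  list(cy = (Y + 1) / 2, cx = (X + 1) / 2,
       a = 0.46 * X, b = 0.40 * Y, theta = 0)
}

.ellipseMask <- function(shape, ell) {
  yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
  xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ct <- cos(ell$theta); st <- sin(ell$theta)
  xr <- (xx - ell$cx) * ct + (yy - ell$cy) * st
  yr <- -(xx - ell$cx) * st + (yy - ell$cy) * ct
  (xr / ell$a)^2 + (yr / ell$b)^2 <= 1
}

# DV coordinate as a fraction of the ellipse's minor-axis extent.
.dvFraction <- function(y, ell) 0.5 + (y - ell$cy) / (2 * ell$b)

# Jittered hexagonal lattice of nucleus centres inside the embryo ellipse.
.hexLattice <- function(config, ell) {
  spacingPx <- config@nucleusSpacingUm / config@pixelSizeUm
  rPx <- config@nucleusRadiusUm / config@pixelSizeUm
  dy <- spacingPx * sqrt(3) / 2
  ys <- seq(ell$cy - ell$b, ell$cy + ell$b, by = dy)
  pts <- do.call(rbind, lapply(seq_along(ys), function(i) {
    off <- if (i %% 2 == 0) spacingPx / 2 else 0
    xs <- seq(ell$cx - ell$a + off, ell$cx + ell$a, by = spacingPx)
    cbind(y = ys[i], x = xs)
  }))
  jit <- matrix(stats::rnorm(length(pts), sd = 0.1 * spacingPx), ncol = 2)
  pts <- pts + jit
  margin <- rPx + 2
  keep <- ((pts[, "x"] - ell$cx) / (ell$a - margin))^2 +
    ((pts[, "y"] - ell$cy) / (ell$b - margin))^2 <= 1
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 4)
    stop("image too small to hold at least 4 nuclei")
  pts
}

# Soft-edged disk patch (error-function edge, width `edge` px). Returns the
# patch weights and the index ranges it covers in the full image.
.softDiskPatch <- function(cy, cx, r, shape, edge = 0.5) {
  pad <- ceiling(r + 4 * edge + 1)
  y0 <- max(1L, floor(cy) - pad); y1 <- min(shape[1], ceiling(cy) + pad)
  x0 <- max(1L, floor(cx) - pad); x1 <- min(shape[2], ceiling(cx) + pad)
  if (y0 > y1 || x0 > x1) return(NULL)
  yy <- matrix(y0:y1, y1 - y0 + 1, x1 - x0 + 1)
  xx <- matrix(x0:x1, y1 - y0 + 1, x1 - x0 + 1, byrow = TRUE)
  rr <- sqrt((yy - cy)^2 + (xx - cx)^2)
  w <- stats::pnorm((r - rr) / edge)
  list(y = y0:y1, x = x0:x1, w = w)
}

# Add Gaussian and salt-and-pepper noise in the current RNG scope.
.addNoiseArray <- function(data, noise) {
  if (noise$gaussianSd > 0)
    data <- data + stats::rnorm(length(data), sd = noise$gaussianSd)
  if (isTRUE(noise$poisson))
    data <- array(stats::rpois(length(data), pmax(data, 0)), dim(data))
  if (noise$saltPepperFraction > 0) {
    hit <- which(stats::runif(length(data)) < noise$saltPepperFraction)
    if (length(hit)) {
      salt <- stats::runif(length(hit)) < 0.5
      mx <- max(data)
      data[hit[salt]] <- mx
      data[hit[!salt]] <- 0
    }
  }
  array(pmin(pmax(data, 0), 65535), dim(data))
}

#' Add read noise to a stack
#'
#' Adds Gaussian read noise, optional Poisson resampling, and salt-and-pepper
#' pixel replacement (the configured fraction of pixels set to 0 or the stack
#' maximum, half each), then clips to the 16-bit range. A zero-noise
#' configuration is the identity.
#'
#' @param stack an [ImageStack-class].
#' @param noise list(gaussianSd, poisson, saltPepperFraction).
#' @param seed optional integer; when given the operation is deterministic and
#'   leaves the global RNG untouched.
#' @return A noisy [ImageStack-class].
#' @export
applyNoise <- function(stack, noise, seed = NULL) {
  stopifnot(is.finite(noise$gaussianSd), noise$gaussianSd >= 0,
            noise$saltPepperFraction >= 0)
  run <- function() .addNoiseArray(stack@data, noise)
  data <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  imageStack(data, pixelSize(stack), frameInterval(stack))
}

# Shared layout step: lattice, per-nucleus baselines, per-frame levels.
.layoutNuclei <- function(config) {
  ell <- .embryoEllipse(config)
  pts <- .hexLattice(config, ell)
  g <- config@gradient
  dv <- .dvFraction(pts[, "y"], ell)
  baseline <- g$offset + g$amplitude * exp(-(dv - g$peakPosition)^2 / (2 * g$sigma^2))
  baseline <- pmax(baseline, 1e-6)
  tMin <- (seq_len(config@nFrames) - 1) * config@frameIntervalS / 60
  lev <- t(matrix(vapply(baseline, function(b)
    nuclearLevelModel(tMin, config@perturbation, b, config@frameIntervalS),
    numeric(length(tMin))), nrow = length(tMin)))
  list(ell = ell, pts = pts, dv = dv, baseline = baseline, levels = lev,
       tMin = tMin, rPx = config@nucleusRadiusUm / config@pixelSizeUm)
}

.nucleusPositions <- function(lay, config, t) {
  drift <- config@driftPxPerFrame * (t - 1)
  cbind(y = lay$pts[, "y"] + drift[1], x = lay$pts[, "x"] + drift[2])
}

.isOccluded <- function(config, i, t) {
  for (oc in config@occlusions)
    if (oc$nucleus == i && t %in% oc$frames) return(TRUE)
  FALSE
}

#' Simulate a nuclear-fluorescence movie
#'
#' Renders soft-edged nuclear disks on a jittered hexagonal lattice inside an
#' elliptical embryo, with per-nucleus levels following
#' [nuclearLevelModel()] scaled by the DV Gaussian gradient. For export the
#' cytoplasmic level rises so that total embryo signal is conserved; for
#' degradation both compartments decay. Deterministic under the config seed.
#'
#' @param config a [SimConfig-class].
#' @return list(stack = [ImageStack-class], truth = list(nucleiTracks,
#'   nuclearLevel, embryoEllipse, embryoMask, radiusPx, baseline)).
#' @export
simulateNucleiMovie <- function(config) {
  withr::with_seed(config@seed, {
    lay <- .layoutNuclei(config)
    shape <- config@imageShape
    mask <- .ellipseMask(shape, lay$ell)
    n <- nrow(lay$pts)
    nucAreaPx <- pi * lay$rPx^2
    cytAreaPx <- max(sum(mask) - n * nucAreaPx, 1)
    cyt0 <- 0.35 * mean(lay$baseline)
    mode <- config@perturbation$mode
    cytLevel <- rep(cyt0, config@nFrames)
    if (mode == "export") {
      deficit <- colSums(lay$levels[, 1] - lay$levels) * nucAreaPx
      cytLevel <- cyt0 + deficit / cytAreaPx
    } else if (mode == "degrade") {
      ratio <- nuclearLevelModel(lay$tMin, config@perturbation, 1,
                                 config@frameIntervalS)
      cytLevel <- cyt0 * ratio
    }
    data <- array(0, c(shape, config@nFrames))
    tracks <- vector("list", config@nFrames)
    for (t in seq_len(config@nFrames)) {
      img <- matrix(0, shape[1], shape[2])
      img[mask] <- cytLevel[t]
      pos <- .nucleusPositions(lay, config, t)
      vis <- logical(n)
      for (i in seq_len(n)) {
        if (.isOccluded(config, i, t)) next
        p <- .softDiskPatch(pos[i, 1], pos[i, 2], lay$rPx, shape)
        if (is.null(p)) next
        img[p$y, p$x] <- img[p$y, p$x] + (lay$levels[i, t] - cytLevel[t]) * p$w
        vis[i] <- TRUE
      }
      data[, , t] <- round(pmin(pmax(img, 0), 65535))
      tracks[[t]] <- data.frame(track = seq_len(n), frame = t,
                                y = pos[, 1], x = pos[, 2], visible = vis)
    }
    data <- .addNoiseArray(data, config@noise)
    list(stack = imageStack(data, config@pixelSizeUm, config@frameIntervalS),
         truth = list(nucleiTracks = do.call(rbind, tracks),
                      nuclearLevel = lay$levels,
                      embryoEllipse = lay$ell, embryoMask = mask,
                      radiusPx = lay$rPx, baseline = lay$baseline,
                      timeMin = lay$tMin))
  })
}

#' Simulate an MS2/MCP transcription-focus movie
#'
#' Nuclei inside the configured gene domain are transcriptionally active with
#' probability `activationProb`; each active nucleus carries one
#' diffraction-limited Gaussian spot at a fixed jittered intranuclear
#' position. During a perturbation a spot switches off `deactivationDelayFrames`
#' frames after the nucleus's simulated level falls below
#' `deactivationThreshold` x baseline, and back on (export only) once the
#' level recovers above it.
#'
#' @param config a [SimConfig-class] with a `foci` block.
#' @return list(stack, truth) where truth$fociTruth is
#'   data.frame(frame, nucleus, y, x) of true active-spot centroids and
#'   truth$activeMatrix the nucleus x frame activity matrix.
#' @export
simulateFociMovie <- function(config) {
  withr::with_seed(config@seed, {
    lay <- .layoutNuclei(config)
    shape <- config@imageShape
    mask <- .ellipseMask(shape, lay$ell)
    fc <- config@foci
    n <- nrow(lay$pts)
    inDomain <- rep(FALSE, n)
    for (iv in fc$domain)
      inDomain <- inDomain | (lay$dv >= iv[1] & lay$dv <= iv[2])
    if (!any(inDomain)) stop("gene domain contains no nuclei")
    active0 <- inDomain & stats::runif(n) < fc$activationProb
    # absolute activation threshold: a fraction of the peak nuclear level,
    # so dimmer (more dorsal) nuclei cross it earlier and domain boundaries
    # retract rather than all nuclei switching at once
    below <- lay$levels < fc$deactivationThreshold * max(lay$baseline)
    delay <- fc$deactivationDelayFrames
    on <- matrix(FALSE, n, config@nFrames)
    for (t in seq_len(config@nFrames)) {
      tRef <- max(1L, t - delay)
      on[, t] <- active0 & !below[, tRef]
    }
    # fixed intranuclear spot offset, uniform within half the nuclear radius
    ang <- stats::runif(n, 0, 2 * pi)
    rad <- lay$rPx * 0.5 * sqrt(stats::runif(n))
    spotOff <- cbind(y = rad * sin(ang), x = rad * cos(ang))
    spotSigmaPx <- fc$spotSigmaUm / config@pixelSizeUm
    nucLevel <- 800; cytLevel <- 300
    data <- array(0, c(shape, config@nFrames))
    fociTruth <- vector("list", config@nFrames)
    for (t in seq_len(config@nFrames)) {
      img <- matrix(0, shape[1], shape[2])
      img[mask] <- cytLevel
      pos <- .nucleusPositions(lay, config, t)
      for (i in seq_len(n)) {
        p <- .softDiskPatch(pos[i, 1], pos[i, 2], lay$rPx, shape)
        if (!is.null(p))
          img[p$y, p$x] <- img[p$y, p$x] + (nucLevel - cytLevel) * p$w
      }
      act <- which(on[, t])
      if (length(act)) {
        sy <- pos[act, 1] + spotOff[act, 1]
        sx <- pos[act, 2] + spotOff[act, 2]
        for (k in seq_along(act)) {
          p <- .softDiskPatch(sy[k], sx[k], 3 * spotSigmaPx, shape, edge = 0.5)
          if (is.null(p)) next
          yy <- matrix(p$y, length(p$y), length(p$x))
          xx <- matrix(p$x, length(p$y), length(p$x), byrow = TRUE)
          g <- exp(-((yy - sy[k])^2 + (xx - sx[k])^2) / (2 * spotSigmaPx^2))
          img[p$y, p$x] <- img[p$y, p$x] + fc$spotAmplitude * g
        }
        fociTruth[[t]] <- data.frame(frame = t, nucleus = act, y = sy, x = sx)
      } else {
        fociTruth[[t]] <- data.frame(frame = integer(), nucleus = integer(),
                                     y = numeric(), x = numeric())
      }
      data[, , t] <- round(pmin(pmax(img, 0), 65535))
    }
    data <- .addNoiseArray(data, config@noise)
    list(stack = imageStack(data, config@pixelSizeUm, config@frameIntervalS),
         truth = list(fociTruth = do.call(rbind, fociTruth),
                      activeMatrix = on, inDomain = inDomain,
                      nucleiTracks = NULL, embryoEllipse = lay$ell,
                      embryoMask = mask, radiusPx = lay$rPx,
                      nuclearLevel = lay$levels, timeMin = lay$tMin))
  })
}

#' Simulate a FRAP movie
#'
#' High-zoom field entirely inside the embryo. Nuclei whose centre lies in
#' the bleach ROI ramp down to I_ss - alpha over the bleach frames and then
#' recover as I(t) = I_ss - alpha * exp(-beta * t) with t measured from the
#' end of bleaching; all other nuclei sit at the steady level I_ss.
#'
#' @param config a [SimConfig-class], typically from [frapConfig()].
#' @param bleachRoi numeric c(y, x, r) circle in px.
#' @param bleachFrames integer frame range of the bleach.
#' @param frapParams c(Iss, alpha, beta) with beta in 1/min, alpha <= Iss.
#' @return list(stack, truth) with truth$frapParams and truth$bleached ids.
#' @export
simulateFrapMovie <- function(config, bleachRoi, bleachFrames,
                              frapParams = c(Iss = 8628, alpha = 7807,
                                             beta = 0.23)) {
  stopifnot(all(frapParams > 0), frapParams[2] <= frapParams[1],
            min(bleachFrames) >= 1, max(bleachFrames) <= config@nFrames)
  Iss <- frapParams[[1]]; alpha <- frapParams[[2]]; beta <- frapParams[[3]]
  withr::with_seed(config@seed, {
    shape <- config@imageShape
    # field of view entirely inside the embryo: no visible boundary
    ell <- list(cy = (shape[1] + 1) / 2, cx = (shape[2] + 1) / 2,
                a = 10 * shape[2], b = 10 * shape[1], theta = 0)
    cfgFlat <- config
    cfgFlat@gradient <- list(amplitude = 0, peakPosition = 0.5, sigma = 0.2,
                             offset = Iss)
    pts <- .hexLattice(cfgFlat, list(cy = ell$cy, cx = ell$cx,
                                     a = 0.49 * shape[2], b = 0.49 * shape[1],
                                     theta = 0))
    rPx <- config@nucleusRadiusUm / config@pixelSizeUm
    dRoi <- sqrt((pts[, "y"] - bleachRoi[1])^2 + (pts[, "x"] - bleachRoi[2])^2)
    bleached <- which(dRoi <= bleachRoi[3])
    if (!length(bleached)) stop("bleach ROI contains no nuclei")
    tMin <- (seq_len(config@nFrames) - 1) * config@frameIntervalS / 60
    tBleachEnd <- tMin[max(bleachFrames)]
    lev <- matrix(Iss, nrow(pts), config@nFrames)
    for (t in seq_len(config@nFrames)) {
      if (t %in% bleachFrames) {
        frac <- match(t, bleachFrames) / length(bleachFrames)
        lev[bleached, t] <- Iss - alpha * frac
      } else if (t > max(bleachFrames)) {
        lev[bleached, t] <- Iss - alpha * exp(-beta * (tMin[t] - tBleachEnd))
      }
    }
    cyt <- 0.5 * Iss
    data <- array(0, c(shape, config@nFrames))
    for (t in seq_len(config@nFrames)) {
      img <- matrix(cyt, shape[1], shape[2])
      for (i in seq_len(nrow(pts))) {
        p <- .softDiskPatch(pts[i, 1], pts[i, 2], rPx, shape)
        if (!is.null(p))
          img[p$y, p$x] <- img[p$y, p$x] + (lev[i, t] - cyt) * p$w
      }
      data[, , t] <- round(pmin(pmax(img, 0), 65535))
    }
    data <- .addNoiseArray(data, config@noise)
    list(stack = imageStack(data, config@pixelSizeUm, config@frameIntervalS),
         truth = list(frapParams = c(Iss = Iss, alpha = alpha, beta = beta),
                      bleached = bleached, positions = pts,
                      nuclearLevel = lev, radiusPx = rPx, timeMin = tMin,
                      bleachFrames = bleachFrames))
  })
}

#' Simulate a fixed cross-section embryo image
#'
#' Renders the peripheral ring of nuclei of an embryo cross-section (nuclear
#' channel) plus up to three gene-expression channels, each occupying one or
#' more angular intervals of the embryo periphery. Nuclear intensities follow
#' the configured DV Gaussian gradient as a function of normalized angular
#' position (0 at the ventral-most point).
#'
#' @param config a [SimConfig-class] (view "cross-section-profile").
#' @param channels list of list(name, intervals) where intervals is a list of
#'   c(from, to) angular fractions in [0, 1).
#' @return list(channels = list(nuclear = matrix, expression = named list of
#'   matrices), truth = list(gradientParams, trueWidths, midEllipse, ...),
#'   pixelSizeUm).
#' @export
simulateFixedEmbryo <- function(config,
                                channels = list(list(name = "sna",
                                                     intervals = list(c(0.92, 0.08))))) {
  if (length(channels) > 3) stop("at most 3 expression channels supported")
  withr::with_seed(config@seed, {
    shape <- config@imageShape
    outer <- list(cy = (shape[1] + 1) / 2, cx = (shape[2] + 1) / 2,
                  a = 0.45 * shape[2], b = 0.38 * shape[1], theta = 0)
    rhoIn <- 0.80; rhoMid <- 0.90
    mid <- list(cy = outer$cy, cx = outer$cx, a = rhoMid * outer$a,
                b = rhoMid * outer$b, theta = 0)
    g <- config@gradient
    rPx <- config@nucleusRadiusUm / config@pixelSizeUm
    # nuclei along the mid-ring ellipse, spaced ~nucleusSpacingUm apart
    per <- ellipseArcLength(mid, 0, 2 * pi)
    nNuc <- max(8, floor(per / (config@nucleusSpacingUm / config@pixelSizeUm)))
    phi <- seq(0, 2 * pi, length.out = nNuc + 1)[-(nNuc + 1)]
    ny <- mid$cy + mid$b * sin(phi)
    nx <- mid$cx + mid$a * cos(phi)
    frac <- ((phi - pi / 2) %% (2 * pi)) / (2 * pi)
    dcirc <- pmin(abs(frac - g$peakPosition),
                  1 - abs(frac - g$peakPosition))
    nucLev <- g$offset + g$amplitude * exp(-dcirc^2 / (2 * g$sigma^2))
    nuclear <- matrix(0, shape[1], shape[2])
    for (i in seq_len(nNuc)) {
      p <- .softDiskPatch(ny[i], nx[i], rPx, shape)
      if (!is.null(p))
        nuclear[p$y, p$x] <- pmax(nuclear[p$y, p$x], nucLev[i] * p$w)
    }
    # angular-fraction and elliptical-radius fields for band rendering
    yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
    xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    ey <- (yy - outer$cy) / outer$b
    ex <- (xx - outer$cx) / outer$a
    rho <- sqrt(ex^2 + ey^2)
    fracImg <- ((atan2(ey, ex) - pi / 2) %% (2 * pi)) / (2 * pi)
    band <- rho >= rhoIn & rho <= 1
    expr <- list()
    trueWidths <- list()
    for (ch in channels) {
      img <- matrix(0, shape[1], shape[2])
      w <- numeric()
      for (iv in ch$intervals) {
        if (iv[1] <= iv[2]) {
          inAng <- fracImg >= iv[1] & fracImg <= iv[2]
        } else {
          inAng <- fracImg >= iv[1] | fracImg <= iv[2]
        }
        img[band & inAng] <- 1000
        th <- 2 * pi * c(iv[1], if (iv[2] >= iv[1]) iv[2] else iv[2] + 1) + pi / 2
        w <- c(w, ellipseArcLength(mid, th[1], th[2]) / per)
      }
      expr[[ch$name]] <- .addNoiseArray(array(img, c(shape, 1)),
                                        config@noise)[, , 1]
      trueWidths[[ch$name]] <- w
    }
    nuclear <- .addNoiseArray(array(nuclear, c(shape, 1)), config@noise)[, , 1]
    list(channels = list(nuclear = nuclear, expression = expr),
         truth = list(gradientParams = c(amplitude = g$amplitude,
                                         mu = g$peakPosition,
                                         sigma = g$sigma, offset = g$offset),
                      trueWidths = trueWidths, midEllipse = mid,
                      outerEllipse = outer, rhoInner = rhoIn,
                      nucleusAngles = frac, nucleusLevels = nucLev),
         pixelSizeUm = config@pixelSizeUm)
  })
}
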