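#' @import methods
NULL

#' Time-lapse image stack
#'
#' Container for a single-channel time-lapse (or single-frame) image with its
#' physical calibration. Pixel data are stored as a numeric Y x X x T array in
#' arbitrary units on the 16-bit scale (values in [0, 65535]); frames are
#' written to disk as one TIFF page each.
#'
#' @slot data numeric array, dim = c(Y, X, T), all values >= 0.
#' @slot pixelSizeUm pixel edge length in micrometres.
#' @slot frameIntervalS time between consecutive frames in seconds.
#'
#' @seealso [imageStack()], [stackFrame()], [readStack()], [writeStack()]
#' @export
setClass("ImageStack",
  representation(
    data = "array",
    pixelSizeUm = "numeric",
    frameIntervalS = "numeric"
  )
)

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a Y x X x T array")
  else if (dim(object@data)[3L] < 1L)
    msg <- c(msg, "stack must contain at least one frame")
  if (any(!is.finite(object@data)) || any(object@data < 0))
    msg <- c(msg, "intensities must be finite and non-negative")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (length(object@frameIntervalS) != 1L || object@frameIntervalS <= 0)
    msg <- c(msg, "frameIntervalS must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Synthetic-embryo simulation configuration
#'
#' Parameters of the synthetic embryo generator. Defaults mirror the live
#' acquisition regime (512 x 512 px, 0.29 um/px, 25 s/frame); FRAP movies use
#' the high-zoom regime (0.100 um/px, 2 s/frame) via [frapConfig()].
#'
#' The `perturbation` list (see [perturbation()]) selects one of three nuclear
#' dynamics: `"none"`, light-driven nuclear `"export"` with single-exponential
#' re-import after light-off, or light-driven `"degrade"` with a short
#' post-light delay and no recovery.
#'
#' @slot view one of "ventral", "dorsolateral", "cross-section-profile".
#' @slot imageShape integer c(Y, X) in pixels.
#' @slot pixelSizeUm,frameIntervalS physical calibration (um/px, s).
#' @slot nFrames number of frames.
#' @slot nucleusRadiusUm,nucleusSpacingUm nuclear radius and hexagonal lattice
#'   spacing in micrometres.
#' @slot gradient list(amplitude, peakPosition, sigma, offset): dorsal-ventral
#'   Gaussian profile of nuclear levels; positions are fractions of the DV
#'   coordinate.
#' @slot perturbation list, see [perturbation()].
#' @slot foci list(spotSigmaUm, spotAmplitude, domain, activationProb,
#'   deactivationThreshold, deactivationDelayFrames): MS2 focus rendering and
#'   activation rules.
#' @slot noise list(gaussianSd, poisson, saltPepperFraction).
#' @slot driftPxPerFrame numeric c(dy, dx): rigid nuclear drift per frame.
#' @slot occlusions list of list(nucleus, frames): scripted invisibility
#'   windows, used to exercise track gap closing.
#' @slot seed integer RNG seed; identical (config, seed) gives byte-identical
#'   output.
#'
#' @export
setClass("SimConfig",
  representation(
    view = "character",
    imageShape = "integer",
    pixelSizeUm = "numeric",
    frameIntervalS = "numeric",
    nFrames = "integer",
    nucleusRadiusUm = "numeric",
    nucleusSpacingUm = "numeric",
    gradient = "list",
    perturbation = "list",
    foci = "list",
    noise = "list",
    driftPxPerFrame = "numeric",
    occlusions = "list",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (!object@view %in% c("ventral", "dorsolateral", "cross-section-profile"))
    msg <- c(msg, "unknown view")
  if (length(object@imageShape) != 2L || any(object@imageShape < 8L))
    msg <- c(msg, "imageShape must be c(Y, X) with both >= 8")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (object@frameIntervalS <= 0) msg <- c(msg, "frameIntervalS must be > 0")
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (object@nucleusSpacingUm < 2 * object@nucleusRadiusUm * 0.9)
    msg <- c(msg, "nucleusSpacingUm must be >= 1.8 * nucleusRadiusUm")
  g <- object@gradient
  if (!all(c("amplitude", "peakPosition", "sigma", "offset") %in% names(g)))
    msg <- c(msg, "gradient needs amplitude, peakPosition, sigma, offset")
  else if (g$amplitude < 0 || g$offset < 0 || g$sigma <= 0)
    msg <- c(msg, "gradient amplitudes must be >= 0 and sigma > 0")
  p <- object@perturbation
  pmsg <- .validatePerturbation(p, object@nFrames)
  msg <- c(msg, pmsg)
  nz <- object@noise
  if (nz$saltPepperFraction < 0 || nz$saltPepperFraction > 0.05)
    msg <- c(msg, "saltPepperFraction must lie in [0, 0.05]")
  if (nz$gaussianSd < 0) msg <- c(msg, "gaussianSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Linked nucleus tracks
#'
#' Result of [linkTracks()]: per-nucleus time series of centroid position and
#' mean intensity, with a record of every bridged gap.
#'
#' @slot tracks data.frame(track, frame, y, x, area, meanIntensity).
#' @slot gaps data.frame(track, from, to): frame ranges bridged by gap closing
#'   (all of length <= the gap-closing horizon).
#' @slot nInputFrames number of frames in the source movie.
#' @slot radius the matching cutoff radius (px) used for linking.
#'
#' @export
setClass("TrackSet",
  representation(
    tracks = "data.frame",
    gaps = "data.frame",
    nInputFrames = "integer",
    radius = "numeric"
  )
)

setValidity("TrackSet", function(object) {
  msg <- character()
  tr <- object@tracks
  if (nrow(tr)) {
    bad <- vapply(split(tr$frame, tr$track),
                  function(f) any(diff(f) <= 0), logical(1))
    if (any(bad)) msg <- c(msg, "frames must be strictly increasing per track")
  }
  if (nrow(object@gaps) &&
      any(object@gaps$to - object@gaps$from + 1L > 10L))
    msg <- c(msg, "bridged gaps must be <= 10 frames")
  if (length(msg)) msg else TRUE
})

#' Single-exponential recovery fit
#'
#' Parameters of the recovery model I(t) = I_ss - alpha * exp(-beta * t)
#' fitted to an intensity trace, where I_ss is the steady-state intensity,
#' alpha the difference between initial and steady-state intensity, and beta
#' the inverse recovery time (1/min).
#'
#' @slot Iss steady-state intensity (a.u.).
#' @slot alpha recovery depth (a.u., >= 0).
#' @slot beta inverse recovery time (1/min, >= 0).
#' @slot fitWindow integer indices of the trace points used.
#' @slot rss residual sum of squares.
#' @slot converged logical.
#'
#' @export
setClass("ExpFitResult",
  representation(
    Iss = "numeric",
    alpha = "numeric",
    beta = "numeric",
    fitWindow = "integer",
    rss = "numeric",
    converged = "logical"
  )
)

setValidity("ExpFitResult", function(object) {
  msg <- character()
  if (object@beta < 0) msg <- c(msg, "beta must be >= 0")
  if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
  if (length(object@fitWindow) == 0L) msg <- c(msg, "fit window is empty")
  if (length(msg)) msg else TRUE
})

.validatePerturbation <- function(p, nFrames) {
  msg <- character()
  need <- c("mode", "lightOnFrame", "lightOffFrame", "exportRate",
            "reimportRate", "degradeRate", "degradePostLightDelay",
            "exportFloorFraction")
  if (!all(need %in% names(p)))
    return("perturbation is missing fields; build it with perturbation()")
  if (!p$mode %in% c("none", "export", "degrade"))
    msg <- c(msg, "perturbation mode must be none, export or degrade")
  if (p$mode != "none") {
    if (!(p$lightOnFrame < p$lightOffFrame && p$lightOffFrame <= nFrames))
      msg <- c(msg, "need lightOnFrame < lightOffFrame <= nFrames")
  }
  if (any(c(p$exportRate, p$reimportRate, p$degradeRate) < 0))
    msg <- c(msg, "perturbation rates must be >= 0")
  msg
}
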