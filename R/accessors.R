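# Constructors, accessors and show methods for the core classes.

#' Create an ImageStack
#'
#' @param data numeric Y x X x T array (a Y x X matrix is promoted to T = 1).
#' @param pixelSizeUm pixel size in micrometres.
#' @param frameIntervalS frame interval in seconds.
#' @return An [ImageStack-class] object.
#' @examples
#' s <- imageStack(array(0, c(8, 8, 2)), pixelSizeUm = 0.29, frameIntervalS = 25)
#' nFrames(s)
#' @export
imageStack <- function(data, pixelSizeUm, frameIntervalS) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  new("ImageStack", data = data, pixelSizeUm = pixelSizeUm,
      frameIntervalS = frameIntervalS)
}

#' @rdname imageStack
#' @param x an ImageStack.
#' @export
nFrames <- function(x) dim(x@data)[3L]

#' @rdname imageStack
#' @export
pixelSize <- function(x) x@pixelSizeUm

#' @rdname imageStack
#' @export
frameInterval <- function(x) x@frameIntervalS

#' @rdname imageStack
#' @param t frame index (1-based).
#' @export
stackFrame <- function(x, t) {
  stopifnot(t >= 1L, t <= nFrames(x))
  x@data[, , t]
}

#' @rdname imageStack
#' @export
stackData <- function(x) x@data

#' Times of the frames of a stack, in minutes from frame 1
#' @param x an ImageStack or a SimConfig.
#' @export
frameTimesMin <- function(x) {
  if (is(x, "ImageStack"))
    return((seq_len(nFrames(x)) - 1) * frameInterval(x) / 60)
  (seq_len(x@nFrames) - 1) * x@frameIntervalS / 60
}

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "ImageStack: %d x %d px, %d frame(s), %.3g um/px, %.3g s/frame\n",
    d[1], d[2], d[3], object@pixelSizeUm, object@frameIntervalS))
  cat(sprintf("  intensity range [%.1f, %.1f] a.u.\n",
              min(object@data), max(object@data)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig (%s view): %d x %d px, %d frames, %.3g um/px, %.3g s/frame\n",
    object@view, object@imageShape[1], object@imageShape[2], object@nFrames,
    object@pixelSizeUm, object@frameIntervalS))
  cat(sprintf("  nuclei: r = %.2f um, spacing = %.2f um; perturbation: %s; seed %d\n",
              object@nucleusRadiusUm, object@nucleusSpacingUm,
              object@perturbation$mode, object@seed))
})

setMethod("show", "TrackSet", function(object) {
  cat(sprintf("TrackSet: %d track(s) over %d frames, %d bridged gap(s), r = %.2f px\n",
              length(unique(object@tracks$track)), object@nInputFrames,
              nrow(object@gaps), object@radius))
})

setMethod("show", "ExpFitResult", function(object) {
  cat(sprintf(
    "ExpFitResult: I(t) = %.4g - %.4g * exp(-%.4g t); rss = %.4g (%s)\n",
    object@Iss, object@alpha, object@beta, object@rss,
    if (object@converged) "converged" else "NOT converged"))
})

#' Accessors for ExpFitResult
#'
#' `steadyState()`, `amplitude()` and `rateConstant()` return I_ss, alpha and
#' beta (1/min); `fitCoef()` returns all three as a named vector.
#'
#' @param fit an [ExpFitResult-class].
#' @export
steadyState <- function(fit) fit@Iss

#' @rdname steadyState
#' @export
amplitude <- function(fit) fit@alpha

#' @rdname steadyState
#' @export
rateConstant <- function(fit) fit@beta

#' @rdname steadyState
#' @export
fitCoef <- function(fit) c(Iss = fit@Iss, alpha = fit@alpha, beta = fit@beta)

#' Accessors for TrackSet
#'
#' `trackTable()` returns the long-format track table; `trackGaps()` the
#' bridged gap records; `trackIds()` the track identifiers.
#'
#' @param x a [TrackSet-class].
#' @export
trackTable <- function(x) x@tracks

#' @rdname trackTable
#' @export
trackGaps <- function(x) x@gaps

#' @rdname trackTable
#' @export
trackIds <- function(x) sort(unique(x@tracks$track))
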