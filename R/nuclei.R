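# Nuclei segmentation, embryo-ellipse fitting, midline-band filtering,
# mean-intensity time series, and nearest-neighbour tracking with gap closing.

#' Nucleus segmentation parameters
#'
#' @param logSigmaPx Laplacian-of-Gaussian scale: 4 for the population view,
#'   10 for the high-zoom (FRAP) view.
#' @param logK segmentation keeps pixels where the LoG response is below
#'   -logK standard deviations (interior of the zero-crossing ring).
#' @param minAreaPx,maxAreaPx size gate; when NULL they default to
#'   [0.25, 4] x the median object area of the reference frame.
#' @param carryForward reuse the previous frame's segmentation when a frame
#'   yields no objects (e.g. when the blue light switches).
#' @param embryoBlurSigmaPx blur used for embryo-boundary detection.
#' @param embryoNormThreshold normalized threshold for the embryo boundary.
#' @param midlineBandPx half-width of the analysis band about the midline.
#' @export
segParams <- function(logSigmaPx = 4, logK = 0.5, minAreaPx = NULL,
                      maxAreaPx = NULL, carryForward = TRUE,
                      embryoBlurSigmaPx = 2, embryoNormThreshold = 0.005,
                      midlineBandPx = 100) {
  stopifnot(logSigmaPx > 0, embryoNormThreshold > 0, embryoNormThreshold < 1)
  list(logSigmaPx = logSigmaPx, logK = logK, minAreaPx = minAreaPx,
       maxAreaPx = maxAreaPx, carryForward = carryForward,
       embryoBlurSigmaPx = embryoBlurSigmaPx,
       embryoNormThreshold = embryoNormThreshold,
       midlineBandPx = midlineBandPx)
}

# Object table (label, y, x, area, meanIntensity) from a label image.
.labelObjects <- function(labelImage, image) {
  n <- max(labelImage)
  if (n == 0)
    return(data.frame(label = integer(), y = numeric(), x = numeric(),
                      area = numeric(), meanIntensity = numeric()))
  idx <- which(labelImage > 0)
  lv <- labelImage[idx]
  ys <- ((idx - 1) %% nrow(labelImage)) + 1
  xs <- ((idx - 1) %/% nrow(labelImage)) + 1
  data.frame(label = as.integer(names(tapply(ys, lv, mean))),
             y = as.numeric(tapply(ys, lv, mean)),
             x = as.numeric(tapply(xs, lv, mean)),
             area = as.numeric(tabulate(lv)[sort(unique(lv))]),
             meanIntensity = as.numeric(tapply(image[idx], lv, mean)),
             row.names = NULL)
}

#' Segment nuclei in a single frame
#'
#' Laplacian-of-Gaussian segmentation at `logSigmaPx` (interior of the
#' zero-crossing ring of the response), hole filling, morphological opening,
#' watershed splitting of touching nuclei, and a size gate. If no objects
#' survive and `carryForward` is on, the previous frame's label image is
#' reused (intensities are re-measured on the current frame).
#'
#' @param image Y x X matrix.
#' @param params a [segParams()] list.
#' @param prev previous frame's result, or NULL.
#' @return list(labelImage, objects = data.frame(label, y, x, area,
#'   meanIntensity), carriedForward).
#' @export
segmentNucleiFrame <- function(image, params = segParams(), prev = NULL) {
  mask <- .logInteriorMask(image, params$logSigmaPx, params$logK)
  lab <- matrix(0L, nrow(image), ncol(image))
  if (any(mask)) {
    mask <- EBImage::fillHull(mask)
    # opening at the LoG scale removes thin edge bands (e.g. the embryo
    # outline) while leaving nucleus-sized blobs intact
    br <- 2L * ceiling(params$logSigmaPx) + 1L
    mask <- EBImage::opening(mask, EBImage::makeBrush(br, "disc")) > 0
    if (any(mask)) {
      ws <- EBImage::watershed(EBImage::distmap(mask), tolerance = 1, ext = 1)
      areas <- tabulate(ws[ws > 0])
      lo <- params$minAreaPx; hi <- params$maxAreaPx
      if (is.null(lo) || is.null(hi)) {
        med <- stats::median(areas)
        if (is.null(lo)) lo <- 0.25 * med
        if (is.null(hi)) hi <- 4 * med
      }
      bad <- which(areas < lo | areas > hi)
      ws[ws %in% bad] <- 0L
      lab <- matrix(as.integer(ws), nrow(image))
    }
  }
  if (max(lab) == 0) {
    if (isTRUE(params$carryForward) && !is.null(prev)) {
      return(list(labelImage = prev$labelImage,
                  objects = .labelObjects(prev$labelImage, image),
                  carriedForward = TRUE))
    }
    stop("no nuclei detected and no previous segmentation to carry forward")
  }
  list(labelImage = lab, objects = .labelObjects(lab, image),
       carriedForward = FALSE)
}

#' Segment nuclei in every frame of a stack
#'
#' The size gate is frozen from the first frame's median object area so the
#' gate does not drift with nuclear intensity over the movie.
#'
#' @param stack an [ImageStack-class].
#' @param params a [segParams()] list.
#' @return A list of per-frame [segmentNucleiFrame()] results.
#' @export
segmentNuclei <- function(stack, params = segParams()) {
  first <- segmentNucleiFrame(stackFrame(stack, 1), params, prev = NULL)
  if (is.null(params$minAreaPx) || is.null(params$maxAreaPx)) {
    med <- stats::median(first$objects$area)
    if (is.null(params$minAreaPx)) params$minAreaPx <- 0.25 * med
    if (is.null(params$maxAreaPx)) params$maxAreaPx <- 4 * med
  }
  out <- vector("list", nFrames(stack))
  out[[1]] <- first
  prev <- first
  for (t in seq_len(nFrames(stack))[-1]) {
    prev <- segmentNucleiFrame(stackFrame(stack, t), params, prev = prev)
    out[[t]] <- prev
  }
  out
}

#' Fit the embryo outline with an ellipse
#'
#' Averages the stack over time (the mean projection is robust to noise
#' extremes, unlike a max projection over many frames), blurs, normalizes to
#' [0, 1], thresholds at the normalized threshold (default 0.005), opens and
#' closes morphologically, and fits a direct least-squares ellipse to the
#' boundary of the largest component.
#'
#' @param stack an [ImageStack-class] (or Y x X matrix).
#' @param params a [segParams()] list.
#' @return list(cy, cx, a, b, theta).
#' @export
fitEmbryoEllipse <- function(stack, params = segParams()) {
  proj <- if (is(stack, "ImageStack")) apply(stack@data, c(1, 2), mean)
          else stack
  blur <- EBImage::gblur(proj, sigma = params$embryoBlurSigmaPx)
  if (max(blur) <= 0) stop("embryo boundary not found: image is dark")
  mask <- (blur / max(blur)) > params$embryoNormThreshold
  br <- EBImage::makeBrush(5, "disc")
  mask <- EBImage::closing(EBImage::opening(mask, br), br) > 0
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) stop("embryo boundary not found: image is dark")
  sizes <- tabulate(lab[lab > 0])
  bnd <- .maskBoundary(lab == which.max(sizes))
  if (nrow(bnd) < 5) stop("degenerate embryo boundary (< 5 points)")
  fitEllipseLS(bnd[, 1], bnd[, 2])
}

#' Keep nuclei within a band about the embryo midline
#'
#' The midline is the major-axis line of the fitted embryo ellipse; objects
#' are kept when the absolute perpendicular distance of their centroid to
#' that line is at most `bandPx` (inclusive).
#'
#' @param objects data.frame with y, x columns.
#' @param ellipse list(cy, cx, a, b, theta).
#' @param bandPx band half-width in px.
#' @return The filtered objects table (with a `midlineDist` column).
#' @export
midlineBandFilter <- function(objects, ellipse, bandPx = 100) {
  d <- -(objects$x - ellipse$cx) * sin(ellipse$theta) +
    (objects$y - ellipse$cy) * cos(ellipse$theta)
  objects$midlineDist <- d
  objects[abs(d) <= bandPx, , drop = FALSE]
}

#' Mean +/- s.d. nuclear-intensity trace
#'
#' Per frame, the mean and standard deviation over (optionally midline-band
#' restricted) nuclei of the per-nucleus mean intensity. Frames with no
#' in-band nuclei are reported as NA, not zero.
#'
#' @param segmentations list from [segmentNuclei()].
#' @param frameIntervalS frame interval (s).
#' @param ellipse optional embryo ellipse enabling the midline-band filter.
#' @param bandPx band half-width in px.
#' @return data.frame(frame, timeMin, mean, sd, n).
#' @export
intensityTimeseries <- function(segmentations, frameIntervalS,
                                ellipse = NULL, bandPx = 100) {
  rows <- lapply(seq_along(segmentations), function(t) {
    obj <- segmentations[[t]]$objects
    if (!is.null(ellipse)) obj <- midlineBandFilter(obj, ellipse, bandPx)
    if (nrow(obj) == 0)
      return(data.frame(frame = t, mean = NA_real_, sd = NA_real_, n = 0L))
    data.frame(frame = t, mean = mean(obj$meanIntensity),
               sd = stats::sd(obj$meanIntensity), n = nrow(obj))
  })
  out <- do.call(rbind, rows)
  out$timeMin <- (out$frame - 1) * frameIntervalS / 60
  out[, c("frame", "timeMin", "mean", "sd", "n")]
}

#' Link per-frame nuclei into tracks
#'
#' Greedy one-to-one nearest-neighbour matching between consecutive frames
#' with cutoff equal to the nuclear radius (median sqrt(area/pi) of the first
#' frame); unmatched detections then search open track heads up to `maxGap`
#' time points back (gap closing from the last known centroid, no motion
#' extrapolation). Tracks missing any of the first `firstN` frames, any of
#' the last `lastN` frames, or containing fewer than `minFraction` of all
#' frames are removed, so every retained track gives the fitting stage
#' enough data.
#'
#' @param segmentations list from [segmentNuclei()].
#' @param maxGap largest look-back (time points) for gap closing.
#' @param firstN,lastN leading/trailing frames that must all be present.
#' @param minFraction minimum fraction of frames a track must cover.
#' @param radius matching cutoff in px; default from first-frame areas.
#' @return A [TrackSet-class].
#' @export
linkTracks <- function(segmentations, maxGap = 10L, firstN = 10L,
                       lastN = 10L, minFraction = 0.5, radius = NULL) {
  nT <- length(segmentations)
  stopifnot(nT >= 2)
  objs <- lapply(segmentations, `[[`, "objects")
  if (is.null(radius)) {
    a <- objs[[1]]$area
    if (!length(a)) stop("no objects in the first frame")
    radius <- stats::median(sqrt(a / pi))
  }
  tracks <- list()   # each: rows(list of df rows), lastFrame, lastY, lastX, gaps
  newTrack <- function(row, f) list(frames = f, y = row$y, x = row$x,
                                    area = row$area, mi = row$meanIntensity,
                                    lastFrame = f, lastY = row$y,
                                    lastX = row$x,
                                    gaps = data.frame(from = integer(),
                                                      to = integer()))
  for (i in seq_len(nrow(objs[[1]])))
    tracks[[i]] <- newTrack(objs[[1]][i, ], 1L)
  for (f in seq_len(nT)[-1]) {
    O <- objs[[f]]
    matchedObj <- rep(FALSE, nrow(O))
    matchedTrk <- rep(FALSE, length(tracks))
    assign1 <- function(lastFrames) {
      cand <- which(!matchedTrk &
                      vapply(tracks, function(tr) tr$lastFrame, 0) %in% lastFrames)
      if (!length(cand) || !any(!matchedObj)) return()
      oIdx <- which(!matchedObj)
      dmat <- outer(vapply(tracks[cand], `[[`, 0, "lastY"), O$y[oIdx],
                    FUN = function(a, b) (b - a)^2) +
        outer(vapply(tracks[cand], `[[`, 0, "lastX"), O$x[oIdx],
              FUN = function(a, b) (b - a)^2)
      dmat <- sqrt(dmat)
      repeat {
        m <- which.min(dmat)
        if (!length(m) || dmat[m] > radius) break
        ti <- cand[(m - 1) %% nrow(dmat) + 1]
        oi <- oIdx[(m - 1) %/% nrow(dmat) + 1]
        tr <- tracks[[ti]]
        if (tr$lastFrame < f - 1L)
          tr$gaps <- rbind(tr$gaps,
                           data.frame(from = tr$lastFrame + 1L, to = f - 1L))
        tr$frames <- c(tr$frames, f)
        tr$y <- c(tr$y, O$y[oi]); tr$x <- c(tr$x, O$x[oi])
        tr$area <- c(tr$area, O$area[oi]); tr$mi <- c(tr$mi, O$meanIntensity[oi])
        tr$lastFrame <- f; tr$lastY <- O$y[oi]; tr$lastX <- O$x[oi]
        tracks[[ti]] <<- tr
        matchedTrk[ti] <<- TRUE; matchedObj[oi] <<- TRUE
        dmat[(m - 1) %% nrow(dmat) + 1, ] <- Inf
        dmat[, (m - 1) %/% nrow(dmat) + 1] <- Inf
        if (all(is.infinite(dmat))) break
      }
    }
    assign1(f - 1L)                          # consecutive-frame matching
    if (any(!matchedObj) && maxGap >= 2L)
      assign1((f - maxGap):(f - 2L))         # gap closing, up to maxGap back
    for (oi in which(!matchedObj))
      tracks[[length(tracks) + 1L]] <- newTrack(O[oi, ], f)
  }
  # track-quality filters
  keep <- vapply(tracks, function(tr) {
    all(seq_len(min(firstN, nT)) %in% tr$frames) &&
      all(seq(max(1L, nT - lastN + 1L), nT) %in% tr$frames) &&
      length(tr$frames) >= nT * minFraction
  }, logical(1))
  tracks <- tracks[keep]
  if (length(tracks)) {
    tab <- do.call(rbind, lapply(seq_along(tracks), function(i) {
      tr <- tracks[[i]]
      data.frame(track = i, frame = tr$frames, y = tr$y, x = tr$x,
                 area = tr$area, meanIntensity = tr$mi)
    }))
    gaps <- do.call(rbind, lapply(seq_along(tracks), function(i) {
      g <- tracks[[i]]$gaps
      if (nrow(g)) cbind(track = i, g) else NULL
    }))
    if (is.null(gaps))
      gaps <- data.frame(track = integer(), from = integer(), to = integer())
  } else {
    tab <- data.frame(track = integer(), frame = integer(), y = numeric(),
                      x = numeric(), area = numeric(),
                      meanIntensity = numeric())
    gaps <- data.frame(track = integer(), from = integer(), to = integer())
  }
  new("TrackSet", tracks = tab, gaps = gaps, nInputFrames = as.integer(nT),
      radius = radius)
}
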