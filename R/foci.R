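# Detection and counting of MS2 transcription-site foci with the
# two-threshold scheme and a logarithmically increasing threshold during nc14.

#' Focus-detection parameters
#'
#' @param medianSmallPx odd kernel width of the despeckling median filter.
#' @param medianBgPx odd kernel width of the background-estimating median
#'   filter (much larger than a focus).
#' @param gaussSigmaPx Gaussian blur applied after background subtraction.
#' @param thrLow low (pass-1) threshold on the processed image, a.u.
#' @param thrHighRaw high (pass-2) threshold on the raw image, a.u.
#' @param thrLogCoeff user-defined coefficient of the logarithmic threshold
#'   increase during nc14 (0 disables it).
#' @param nc14StartFrame first frame of nc14 (1-based).
#' @param embryoBlurSigmaPx blur used when segmenting the whole embryo.
#' @param embryoThr optional embryo threshold (a.u.); when NULL Otsu's
#'   threshold of the temporal max projection is used.
#' @return A validated parameter list.
#' @export
fociParams <- function(medianSmallPx = 3L, medianBgPx = 51L,
                       gaussSigmaPx = 1.0, thrLow = 500, thrHighRaw = 2000,
                       thrLogCoeff = 0, nc14StartFrame = 1L,
                       embryoBlurSigmaPx = 3, embryoThr = NULL) {
  stopifnot(medianSmallPx %% 2 == 1, medianBgPx %% 2 == 1,
            medianBgPx > medianSmallPx, medianSmallPx >= 3,
            thrLow > 0, thrHighRaw >= thrLow)
  list(medianSmallPx = as.integer(medianSmallPx),
       medianBgPx = as.integer(medianBgPx),
       gaussSigmaPx = gaussSigmaPx, thrLow = thrLow,
       thrHighRaw = thrHighRaw, thrLogCoeff = thrLogCoeff,
       nc14StartFrame = as.integer(nc14StartFrame),
       minObjectPx = 2L, embryoMinAreaPx = 100L,
       embryoBlurSigmaPx = embryoBlurSigmaPx, embryoThr = embryoThr)
}

#' Segment the whole embryo from a time-lapse stack
#'
#' Max-projects all frames, blurs, thresholds, closes morphologically,
#' discards components below 100 px, and keeps the largest remaining
#' component so that exactly one object -- the embryo -- is detected.
#'
#' @param stack an [ImageStack-class].
#' @param params a [fociParams()] list.
#' @return list(mask = logical Y x X, areaPx).
#' @export
computeEmbryoMask <- function(stack, params = fociParams()) {
  proj <- apply(stack@data, c(1, 2), max)
  if (max(proj) <= 0) stop("no embryo found")
  blur <- EBImage::gblur(proj, sigma = params$embryoBlurSigmaPx)
  thr <- params$embryoThr
  if (is.null(thr)) {
    # half the Otsu threshold: Otsu separates the bright nuclei from
    # everything else, whereas the embryo interior (dim cytoplasm) must be
    # kept; halving lands the cut between background and cytoplasm
    thr <- 0.5 *
      EBImage::otsu(EBImage::Image(blur / max(blur)), range = c(0, 1)) *
      max(blur)
  }
  mask <- blur > thr
  mask <- EBImage::closing(mask, EBImage::makeBrush(5, "disc")) > 0
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) stop("no embryo found")
  sizes <- tabulate(lab[lab > 0])
  sizes[sizes < params$embryoMinAreaPx] <- 0L
  if (all(sizes == 0)) stop("no embryo found")
  keep <- which.max(sizes)
  list(mask = lab == keep, areaPx = sizes[keep])
}

#' Detection threshold schedule
#'
#' Constant at `thrLow` before nc14; from `nc14StartFrame` on it increases
#' logarithmically: thr(f) = thrLow * (1 + coeff * log(1 + (f - start)/n)),
#' compensating the rise in nuclear background intensity over nc14.
#'
#' @param frame 1-based frame index.
#' @param params a [fociParams()] list.
#' @param nNc14Frames number of nc14 frames used to scale the schedule.
#' @return Threshold in a.u.; non-decreasing in `frame`.
#' @export
thresholdSchedule <- function(frame, params, nNc14Frames) {
  stopifnot(nNc14Frames >= 1)
  ifelse(frame < params$nc14StartFrame, params$thrLow,
         params$thrLow * (1 + params$thrLogCoeff *
                            log1p((frame - params$nc14StartFrame) / nNc14Frames)))
}

#' Detect transcription-site foci in one frame
#'
#' Pipeline: despeckling median filter; background subtraction via a large
#' median filter; Gaussian blur; threshold at [thresholdSchedule()];
#' removal of 1-px objects, border-touching objects and objects outside the
#' embryo; and a second pass that retains only objects containing at least
#' one raw pixel above `thrHighRaw` (foci must be detected with both
#' thresholds).
#'
#' @param image Y x X matrix (raw intensities, a.u.).
#' @param embryo result of [computeEmbryoMask()].
#' @param params a [fociParams()] list.
#' @param frame 1-based frame index (drives the threshold schedule).
#' @param nNc14Frames nc14 duration in frames for the schedule.
#' @return data.frame(frame, label, y, x) of focus centroids (unweighted
#'   pixel means); empty when nothing passes.
#' @export
detectFociFrame <- function(image, embryo, params, frame = 1L,
                            nNc14Frames = 100L) {
  stopifnot(all(dim(image) == dim(embryo$mask)))
  empty <- data.frame(frame = integer(), label = integer(),
                      y = numeric(), x = numeric())
  sc <- max(max(image), 1)
  f1 <- EBImage::medianFilter(image / sc, (params$medianSmallPx - 1L) / 2L) * sc
  bg <- EBImage::medianFilter(image / sc, (params$medianBgPx - 1L) / 2L) * sc
  blur <- EBImage::gblur(f1 - bg, sigma = params$gaussSigmaPx)
  thr <- thresholdSchedule(frame, params, nNc14Frames)
  lab <- EBImage::bwlabel(blur > thr)
  nObj <- max(lab)
  if (nObj == 0) return(empty)
  sizes <- tabulate(lab[lab > 0], nbins = nObj)
  keep <- sizes >= params$minObjectPx
  # drop objects touching the frame border
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  keep[border[border > 0]] <- FALSE
  if (!any(keep)) return(empty)
  idx <- which(lab > 0)
  idx <- idx[keep[lab[idx]]]
  lv <- lab[idx]
  ys <- ((idx - 1) %% nrow(lab)) + 1
  xs <- ((idx - 1) %/% nrow(lab)) + 1
  cy <- tapply(ys, lv, mean)
  cx <- tapply(xs, lv, mean)
  labels <- as.integer(names(cy))
  # centroid must lie inside the embryo
  inEmb <- embryo$mask[cbind(pmin(pmax(round(cy), 1), nrow(lab)),
                             pmin(pmax(round(cx), 1), ncol(lab)))]
  # pass 2: at least one raw pixel above the high threshold
  rawMax <- tapply(image[idx], lv, max)
  ok <- inEmb & rawMax > params$thrHighRaw
  if (!any(ok)) return(empty)
  data.frame(frame = as.integer(frame), label = labels[ok],
             y = as.numeric(cy[ok]), x = as.numeric(cx[ok]),
             row.names = NULL)
}

#' Detect foci in every frame of a stack
#'
#' @param stack an [ImageStack-class].
#' @param params a [fociParams()] list.
#' @param nNc14Frames nc14 duration in frames.
#' @param embryo optional precomputed [computeEmbryoMask()] result.
#' @return data.frame(frame, label, y, x) over all frames.
#' @export
detectFoci <- function(stack, params = fociParams(), nNc14Frames = 100L,
                       embryo = NULL) {
  if (is.null(embryo)) embryo <- computeEmbryoMask(stack, params)
  res <- lapply(seq_len(nFrames(stack)), function(t)
    detectFociFrame(stackFrame(stack, t), embryo, params, t, nNc14Frames))
  do.call(rbind, res)
}

#' Instantaneous focus counts over time
#'
#' Counts detected foci per frame (not cumulative) and normalizes by the
#' starting count, the per-embryo normalization used when averaging across
#' embryos.
#'
#' @param foci data.frame with a `frame` column ([detectFoci()] output).
#' @param nFramesTotal total number of movie frames (frames with no
#'   detections count as zero).
#' @param frameIntervalS frame interval in seconds.
#' @return data.frame(frame, timeMin, count, normalized); when the starting
#'   count is zero `normalized` is NA and attribute
#'   `normalizationFailed` is TRUE.
#' @export
countSeries <- function(foci, nFramesTotal, frameIntervalS) {
  counts <- tabulate(foci$frame, nbins = nFramesTotal)
  out <- data.frame(frame = seq_len(nFramesTotal),
                    timeMin = (seq_len(nFramesTotal) - 1) * frameIntervalS / 60,
                    count = counts)
  if (counts[1] > 0) {
    out$normalized <- counts / counts[1]
    attr(out, "normalizationFailed") <- FALSE
  } else {
    out$normalized <- NA_real_
    attr(out, "normalizationFailed") <- TRUE
    warning("starting focus count is zero; reporting raw counts only")
  }
  out
}
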