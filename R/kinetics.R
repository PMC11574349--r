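# Single-exponential recovery fitting for nuclear re-import (after light-off)
# and FRAP, plus rate-constant comparison between conditions.

#' Fit the single-exponential recovery model
#'
#' Nonlinear least squares of I(t) = I_ss - alpha * exp(-beta * (t - t0))
#' over the fit window, with t0 the first window time point.
#' Levenberg-Marquardt with analytic Jacobian, parameter bounds
#' I_ss, alpha, beta >= 0, and initialization I_ss0 = mean of the final 10%
#' of the window, alpha0 = max(I_ss0 - first window value, 0),
#' beta0 = 2 / window duration.
#'
#' @param tMin time in minutes.
#' @param intensity intensities (a.u.), same length.
#' @param window integer indices of the recovery period (default: all
#'   points). Must contain >= 4 points.
#' @return An [ExpFitResult-class]; beta is in 1/min.
#' @export
fitSingleExponential <- function(tMin, intensity, window = seq_along(tMin)) {
  stopifnot(length(tMin) == length(intensity))
  window <- as.integer(window)
  if (length(window) < 4) stop("fit window must contain at least 4 points")
  tw <- tMin[window]; yw <- intensity[window]
  if (any(!is.finite(yw))) stop("non-finite intensities in fit window")
  mu <- mean(yw)
  if (stats::var(yw) < 1e-12 * max(mu^2, 1e-300))
    stop("flat trace, beta unidentifiable")
  t0 <- tw[1]
  td <- tw - t0
  nTail <- max(1L, ceiling(0.1 * length(yw)))
  Iss0 <- mean(utils::tail(yw, nTail))
  a0 <- max(Iss0 - yw[1], 0)
  b0 <- 2 / max(td[length(td)], 1e-6)
  resid <- function(p) p[1] - p[2] * exp(-p[3] * td) - yw
  jac <- function(p) {
    e <- exp(-p[3] * td)
    cbind(1, -e, p[2] * td * e)
  }
  fit <- minpack.lm::nls.lm(par = c(Iss = Iss0, alpha = a0, beta = b0),
                            fn = resid, jac = jac,
                            lower = c(0, 0, 0),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 1000, ptol = 1e-12, ftol = 1e-12))
  p <- fit$par
  new("ExpFitResult", Iss = unname(p[1]), alpha = unname(p[2]),
      beta = unname(p[3]), fitWindow = window, rss = sum(fit$fvec^2),
      converged = fit$info %in% 1:4)
}

#' Per-nucleus recovery fits after light-off
#'
#' Fits the recovery exponential to each track's intensity trace from the
#' light-off frame to the movie end and summarises the parameters across
#' nuclei (mean +/- s.d.), as done when averaging per-nucleus re-import
#' kinetics within an embryo.
#'
#' @param trackSet a [TrackSet-class] (tracks should already have passed the
#'   track-quality filters).
#' @param lightOffFrame 1-based frame where the light went off.
#' @param frameIntervalS frame interval (s).
#' @return list(fits = named list of [ExpFitResult-class], summary =
#'   data.frame(parameter, mean, sd, n)).
#' @export
perNucleusRecovery <- function(trackSet, lightOffFrame, frameIntervalS) {
  tab <- trackTable(trackSet)
  stopifnot(lightOffFrame >= 1, lightOffFrame <= trackSet@nInputFrames)
  ids <- trackIds(trackSet)
  fits <- list()
  for (id in ids) {
    tr <- tab[tab$track == id, ]
    sel <- which(tr$frame >= lightOffFrame)
    if (length(sel) < 4) next
    tMin <- (tr$frame - 1) * frameIntervalS / 60
    f <- try(fitSingleExponential(tMin, tr$meanIntensity, sel), silent = TRUE)
    if (!inherits(f, "try-error")) fits[[as.character(id)]] <- f
  }
  if (length(fits) < 3)
    warning("fewer than 3 usable tracks; summary statistics are fragile")
  pm <- vapply(fits, fitCoef, numeric(3))
  summary <- data.frame(parameter = c("Iss", "alpha", "beta"),
                        mean = if (length(fits)) rowMeans(pm) else NA_real_,
                        sd = if (length(fits)) apply(pm, 1, stats::sd)
                             else NA_real_,
                        n = length(fits), row.names = NULL)
  list(fits = fits, summary = summary)
}

#' Analyse a FRAP movie
#'
#' Segments every frame at the high-zoom LoG scale, selects the nucleus
#' nearest the bleach-ROI centre in the first frame (the centre-most bleached
#' nucleus), tracks it by nearest-neighbour association (carrying the
#' previous position when segmentation fails), and fits the recovery
#' exponential to its mean-intensity trace starting at the first post-bleach
#' frame.
#'
#' @param stack an [ImageStack-class].
#' @param bleachRoi c(y, x, r) in px.
#' @param bleachFrames integer frame range of the bleach.
#' @param params a [segParams()] list (default uses logSigmaPx = 10).
#' @return list(trace = data.frame(frame, timeMin, intensity), fit =
#'   [ExpFitResult-class], bleachFrames).
#' @export
frapAnalyze <- function(stack, bleachRoi, bleachFrames,
                        params = segParams(logSigmaPx = 10)) {
  stopifnot(max(bleachFrames) < nFrames(stack))
  segs <- segmentNuclei(stack, params)
  o1 <- segs[[1]]$objects
  d1 <- sqrt((o1$y - bleachRoi[1])^2 + (o1$x - bleachRoi[2])^2)
  if (!any(d1 <= bleachRoi[3]))
    stop("no nucleus found inside the bleach ROI at the first frame")
  cur <- o1[which.min(d1), ]
  r <- stats::median(sqrt(o1$area / pi))
  curMask <- which(segs[[1]]$labelImage == cur$label)
  trace <- numeric(nFrames(stack))
  trace[1] <- cur$meanIntensity
  for (t in seq_len(nFrames(stack))[-1]) {
    img <- stackFrame(stack, t)
    ot <- segs[[t]]$objects
    d <- sqrt((ot$y - cur$y)^2 + (ot$x - cur$x)^2)
    if (length(d) && min(d) <= r) {
      cur <- ot[which.min(d), ]
      curMask <- which(segs[[t]]$labelImage == cur$label)
      trace[t] <- cur$meanIntensity
    } else {
      # nucleus not segmented this frame (e.g. dimmer than the cytoplasm
      # right after the bleach): measure the current frame over the last
      # known segmentation of this nucleus
      trace[t] <- mean(img[curMask])
    }
  }
  tMin <- frameTimesMin(stack)
  window <- (max(bleachFrames) + 1L):nFrames(stack)
  fit <- fitSingleExponential(tMin, trace, window)
  list(trace = data.frame(frame = seq_len(nFrames(stack)), timeMin = tMin,
                          intensity = trace),
       fit = fit, bleachFrames = bleachFrames)
}

#' Compare recovery rate constants between two conditions
#'
#' Pooled-variance two-sided unpaired t-test on two sets of fitted beta
#' values (e.g. dark vs blue light).
#'
#' @param betasA,betasB numeric vectors (>= 2 each), 1/min.
#' @return See [ttestPooled()].
#' @export
compareRates <- function(betasA, betasB) ttestPooled(betasA, betasB)
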