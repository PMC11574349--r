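# Fixed-embryo geometry: DV intensity profiles, Gaussian gradient fits,
# nuclear-ring segmentation, ellipse fitting and arc-length domain widths.

#' Arc length along an ellipse
#'
#' Numerical quadrature of the ellipse arc-length integrand
#' sqrt(a^2 sin^2(theta) + b^2 cos^2(theta)) between two parametric angles
#' (point at angle theta = centre + (a cos(theta), b sin(theta))).
#'
#' @param ellipse list(cy, cx, a, b, theta).
#' @param theta1,theta2 parametric angles, theta1 < theta2 <= theta1 + 2*pi.
#' @return Arc length in pixels, to ~1e-9 relative accuracy.
#' @examples
#' circ <- list(cy = 0, cx = 0, a = 1, b = 1, theta = 0)
#' ellipseArcLength(circ, 0, pi / 2)  # pi/2
#' @export
ellipseArcLength <- function(ellipse, theta1, theta2) {
  stopifnot(theta1 < theta2, theta2 <= theta1 + 2 * pi + 1e-12)
  a <- ellipse$a; b <- ellipse$b
  f <- function(th) sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2)
  stats::integrate(f, theta1, theta2, rel.tol = 1e-11,
                   subdivisions = 400L)$value
}

#' @rdname ellipseArcLength
#' @export
ellipsePerimeter <- function(ellipse)
  ellipseArcLength(ellipse, 0, 2 * pi)

# Point(s) on an ellipse at parametric angle(s) theta, honouring orientation.
.ellipsePoint <- function(ellipse, theta) {
  ct <- cos(ellipse$theta); st <- sin(ellipse$theta)
  xr <- ellipse$a * cos(theta); yr <- ellipse$b * sin(theta)
  cbind(y = ellipse$cy + xr * st + yr * ct,
        x = ellipse$cx + xr * ct - yr * st)
}

#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to boundary points (y, x) by the direct conic
#' least-squares method (ellipse-specific constraint 4AC - B^2 = 1), then
#' converts the conic to geometric parameters.
#'
#' @param y,x point coordinates (>= 5 points).
#' @return list(cy, cx, a, b, theta) with a >= b > 0; theta is the major-axis
#'   angle in the (x, y) plane.
#' @export
fitEllipseLS <- function(y, x) {
  if (length(y) < 5) stop("need at least 5 points to fit an ellipse")
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  e <- eigen(M)
  cond <- 4 * Re(e$vectors[1, ]) * Re(e$vectors[3, ]) - Re(e$vectors[2, ])^2
  a1 <- Re(e$vectors[, which(cond > 0)[1]])
  coef <- c(a1, as.vector(Tm %*% a1))
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F <- coef[6]
  den <- B^2 - 4 * A * C
  cx0 <- (2 * C * D - B * E) / den
  cy0 <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
  s <- sqrt((A - C)^2 + B^2)
  ax1 <- -sqrt(num * (A + C + s)) / den
  ax2 <- -sqrt(num * (A + C - s)) / den
  theta <- atan2(C - A - s, B)
  aa <- max(ax1, ax2); bb <- min(ax1, ax2)
  if (ax2 > ax1) theta <- theta + pi / 2
  theta <- ((theta + pi / 2) %% pi) - pi / 2
  list(cy = cy0 + my, cx = cx0 + mx, a = aa, b = bb, theta = theta)
}

# Normalized elliptical coordinates of every pixel: radius rho and angular
# fraction (0 at the ventral-most point, increasing counter-clockwise in
# image coordinates).
.ellipticCoords <- function(shape, ellipse) {
  yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
  xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ct <- cos(ellipse$theta); st <- sin(ellipse$theta)
  xr <- (xx - ellipse$cx) * ct + (yy - ellipse$cy) * st
  yr <- -(xx - ellipse$cx) * st + (yy - ellipse$cy) * ct
  ex <- xr / ellipse$a; ey <- yr / ellipse$b
  list(rho = sqrt(ex^2 + ey^2),
       frac = ((atan2(ey, ex) - pi / 2) %% (2 * pi)) / (2 * pi))
}

#' Dorsal-ventral intensity profile around the embryo periphery
#'
#' Bins mean intensity of the peripheral nuclear band by normalized angular
#' position along the embryo ellipse (0 at the ventral-most point), spanning
#' the full DV circumference.
#'
#' @param image Y x X matrix.
#' @param ellipse embryo ellipse, list(cy, cx, a, b, theta).
#' @param nBins number of angular bins (>= 16).
#' @param band c(rhoMin, rhoMax) elliptical-radius band sampled.
#' @return data.frame(position, intensity) with position the bin centre in
#'   [0, 1).
#' @export
dvProfile <- function(image, ellipse, nBins = 64L, band = c(0.75, 1.05)) {
  stopifnot(nBins >= 16L)
  co <- .ellipticCoords(dim(image), ellipse)
  sel <- co$rho >= band[1] & co$rho <= band[2]
  bin <- pmin(floor(co$frac[sel] * nBins), nBins - 1L)
  vals <- tapply(image[sel], factor(bin, levels = 0:(nBins - 1L)), mean)
  data.frame(position = (0:(nBins - 1L) + 0.5) / nBins,
             intensity = as.numeric(vals))
}

#' Fit a Gaussian to a DV intensity profile
#'
#' Least-squares fit of A * exp(-(x - mu)^2 / (2 sigma^2)) + B to a circular
#' profile. The profile is rotated so its empirical maximum sits at 0.5
#' before fitting (avoiding wrap bias at the ventral point), and mu is mapped
#' back afterwards.
#'
#' @param profile data.frame(position, intensity) from [dvProfile()], or any
#'   two-column table (>= 8 points).
#' @return list(amplitude, mu, sigma, offset, rss, converged, lowAmplitude).
#' @export
fitGaussianGradient <- function(profile) {
  x <- profile[[1]]; yv <- profile[[2]]
  ok <- is.finite(yv)
  x <- x[ok]; yv <- yv[ok]
  if (length(x) < 8) stop("need at least 8 profile points")
  shift <- 0.5 - x[which.max(yv)]
  xs <- (x + shift) %% 1
  o <- order(xs); xs <- xs[o]; ys <- yv[o]
  p0 <- c(A = max(ys) - min(ys), mu = 0.5, sigma = 0.125, B = min(ys))
  resid <- function(p) p[1] * exp(-(xs - p[2])^2 / (2 * p[3]^2)) + p[4] - ys
  fit <- minpack.lm::nls.lm(par = p0, fn = resid,
                            lower = c(0, 0, 1e-4, -Inf),
                            upper = c(Inf, 1, 1, Inf),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ptol = 1e-12, ftol = 1e-12))
  p <- fit$par
  muOut <- (p[2] - shift) %% 1
  list(amplitude = unname(p[1]), mu = unname(muOut), sigma = unname(p[3]),
       offset = unname(p[4]), rss = sum(fit$fvec^2),
       converged = fit$info %in% 1:4,
       lowAmplitude = p[1] < stats::sd(ys) + 1e-8)
}

# Laplacian-of-Gaussian kernel (sum-zero), size 2*ceil(3 sigma) + 1.
.logKernel <- function(sigma) {
  h <- ceiling(3 * sigma)
  g <- outer(-h:h, -h:h, function(y, x)
    ((x^2 + y^2 - 2 * sigma^2) / sigma^4) *
      exp(-(x^2 + y^2) / (2 * sigma^2)))
  g - mean(g)
}

# Interior mask of bright structures at scale sigma: pixels inside the
# zero-crossing ring of the LoG response (response strongly negative).
.logInteriorMask <- function(image, sigma, k = 1) {
  resp <- EBImage::filter2(image, .logKernel(sigma))
  thr <- -k * stats::sd(resp)
  resp < thr
}

#' Segment the peripheral nuclear rings of a cross-section image
#'
#' Laplacian-of-Gaussian segmentation at scale `logSigmaPx` of the bright
#' ring of peripheral nuclei; the filled outer disk and the interior disk
#' enclosed by the ring are the two largest filled objects, an ellipse is fit
#' to the boundary of each, and the mid ellipse is their parameter-wise
#' average.
#'
#' @param image nuclear-channel Y x X matrix.
#' @param logSigmaPx LoG scale in pixels (default 20, ring-of-nuclei scale).
#' @return list(outer, inner, mid) ellipses (each list(cy, cx, a, b, theta)).
#' @export
segmentNuclearRings <- function(image, logSigmaPx = 20) {
  ring <- .logInteriorMask(image, logSigmaPx, k = 0.5)
  # connect the individual nuclei of the ring into a closed annulus
  ring <- EBImage::closing(ring,
                           EBImage::makeBrush(2L * ceiling(logSigmaPx / 2) + 1L,
                                              "disc")) > 0
  outerFill <- EBImage::fillHull(ring)
  inner <- outerFill & !ring
  labIn <- EBImage::bwlabel(inner)
  if (max(labIn) < 1 || sum(ring) == sum(outerFill))
    stop("no enclosed interior found: image has no nuclear ring")
  sizes <- tabulate(labIn[labIn > 0])
  innerMask <- labIn == which.max(sizes)
  if (sum(innerMask) < 25)
    stop("no enclosed interior found: image has no nuclear ring")
  # a genuine ring has a dark interior; a solid bright object does not
  if (mean(image[innerMask]) > 0.5 * mean(image[ring]))
    stop("enclosed interior is bright: image is a solid object, not a ring")
  bOuter <- .maskBoundary(outerFill)
  bInner <- .maskBoundary(innerMask)
  if (nrow(bOuter) < 5 || nrow(bInner) < 5)
    stop("degenerate ring boundaries")
  eo <- fitEllipseLS(bOuter[, 1], bOuter[, 2])
  ei <- fitEllipseLS(bInner[, 1], bInner[, 2])
  mid <- list(cy = (eo$cy + ei$cy) / 2, cx = (eo$cx + ei$cx) / 2,
              a = (eo$a + ei$a) / 2, b = (eo$b + ei$b) / 2,
              theta = atan2(mean(sin(2 * c(eo$theta, ei$theta))),
                            mean(cos(2 * c(eo$theta, ei$theta)))) / 2)
  list(outer = eo, inner = ei, mid = mid)
}

# Boundary pixel coordinates (y, x) of a logical mask.
.maskBoundary <- function(mask) {
  er <- EBImage::erode(mask, EBImage::makeBrush(3, "box"))
  which(mask & !er, arr.ind = TRUE)
}

#' Normalized expression-domain widths along the embryo periphery
#'
#' Thresholds an expression channel, removes small background objects, samples
#' the mid-ring ellipse at `nAngles` angular positions, finds the maximal
#' angular runs inside the segmented expression mask, and converts each run
#' to an arc length normalized by the ellipse perimeter. Crossing angles are
#' midpoints between the last sample outside and the first inside.
#'
#' @param exprImage expression-channel Y x X matrix.
#' @param midEllipse mid-ring ellipse from [segmentNuclearRings()].
#' @param threshold intensity threshold segmenting expression.
#' @param gene label carried into the result.
#' @param keepFraction components smaller than this fraction of the largest
#'   are discarded as background.
#' @param nAngles angular sampling density.
#' @return list(gene, widthsNormalized, arcLengthsPx, perimeterPx, crossings).
#' @export
domainWidths <- function(exprImage, midEllipse, threshold, gene = "gene",
                         keepFraction = 0.25, nAngles = 4096L) {
  mask <- exprImage > threshold
  lab <- EBImage::bwlabel(mask)
  per <- ellipsePerimeter(midEllipse)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= keepFraction * max(sizes))
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  theta <- 2 * pi * (seq_len(nAngles) - 1) / nAngles + pi / 2
  pts <- .ellipsePoint(midEllipse, theta)
  iy <- round(pts[, "y"]); ix <- round(pts[, "x"])
  inb <- iy >= 1 & iy <= nrow(mask) & ix >= 1 & ix <= ncol(mask)
  inside <- logical(nAngles)
  inside[inb] <- mask[cbind(iy[inb], ix[inb])]
  emptyRes <- list(gene = gene, widthsNormalized = numeric(),
                   arcLengthsPx = numeric(), perimeterPx = per,
                   crossings = data.frame(thetaStart = numeric(),
                                          thetaEnd = numeric()))
  if (!any(inside)) return(emptyRes)
  if (all(inside)) {
    return(list(gene = gene, widthsNormalized = 1, arcLengthsPx = per,
                perimeterPx = per,
                crossings = data.frame(thetaStart = theta[1],
                                       thetaEnd = theta[1] + 2 * pi)))
  }
  # circular runs of TRUE: rotate so position 1 is outside
  start <- which(!inside)[1]
  rot <- c(inside[start:nAngles], inside[seq_len(start - 1)])
  d <- diff(c(rot, rot[1]))
  starts <- which(d == 1) + 1L       # first inside sample of each run
  ends <- which(d == -1)             # last inside sample of each run
  dth <- 2 * pi / nAngles
  unrot <- function(i) ((i - 1 + start - 1) %% nAngles) + 1L
  res <- lapply(seq_along(starts), function(k) {
    i1 <- unrot(starts[k]); i2 <- unrot(ends[k])
    th1 <- theta[i1] - dth / 2        # midpoint last-outside/first-inside
    th2 <- theta[i2] + dth / 2
    if (th2 <= th1) th2 <- th2 + 2 * pi
    c(th1, th2, ellipseArcLength(midEllipse, th1, th2))
  })
  res <- do.call(rbind, res)
  list(gene = gene, widthsNormalized = res[, 3] / per,
       arcLengthsPx = res[, 3], perimeterPx = per,
       crossings = data.frame(thetaStart = res[, 1], thetaEnd = res[, 2]))
}
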