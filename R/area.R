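# Expression-domain extent from pooled focus centroids: MAD outlier removal,
# convex-hull area, and the nc14 - nc13 area difference.

#' Pool focus centroids over a frame window
#'
#' Concatenates all detected centroids whose frame falls in `window`;
#' duplicates (persistent foci) are preserved.
#'
#' @param foci data.frame(frame, y, x, ...) from [detectFoci()].
#' @param window integer frame range.
#' @return data.frame(y, x).
#' @export
poolCentroids <- function(foci, window) {
  sel <- foci$frame %in% window
  data.frame(y = foci$y[sel], x = foci$x[sel])
}

#' Remove centroid outliers by per-axis MAD
#'
#' A point is removed iff |y - med_y| > k * MAD_y or |x - med_x| > k * MAD_x,
#' with the unscaled median absolute deviation and a strict inequality. An
#' axis with MAD = 0 contributes no removals. This conservative rule discards
#' isolated detections that were likely noise rather than real foci.
#'
#' @param cloud data.frame(y, x).
#' @param k MAD multiplier (default 2).
#' @return The filtered cloud, with attribute `nRemoved`.
#' @export
madFilter <- function(cloud, k = 2) {
  stopifnot(k > 0)
  if (nrow(cloud) == 0) {
    attr(cloud, "nRemoved") <- 0L
    return(cloud)
  }
  out <- rep(FALSE, nrow(cloud))
  for (ax in c("y", "x")) {
    v <- cloud[[ax]]
    m <- stats::median(v)
    madv <- stats::median(abs(v - m))   # unscaled MAD
    if (madv > 0) out <- out | (abs(v - m) > k * madv)
  }
  res <- cloud[!out, , drop = FALSE]
  attr(res, "nRemoved") <- sum(out)
  res
}

#' Convex-hull area of a point cloud
#'
#' Shoelace area over the convex-hull vertex cycle; 0 for fewer than 3
#' non-collinear points.
#'
#' @param cloud data.frame(y, x).
#' @return Area in px^2.
#' @export
hullArea <- function(cloud) {
  if (nrow(cloud) < 3) return(0)
  h <- grDevices::chull(cloud$x, cloud$y)
  if (length(h) < 3) return(0)
  x <- cloud$x[h]; y <- cloud$y[h]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Change in expression area between nuclear cycles
#'
#' Pools centroids per window, applies the MAD filter, takes the convex-hull
#' area, and reports area(nc14) - area(nc13). Subtracting the nc13 area
#' accounts for embryo-to-embryo differences in orientation and field
#' placement.
#'
#' @param foci data.frame(frame, y, x, ...).
#' @param window13,window14 disjoint, ordered frame ranges (nc13; first part
#'   of nc14).
#' @param k MAD multiplier.
#' @return list(areaNc13, areaNc14, deltaArea, nPointsRemoved).
#' @export
deltaArea <- function(foci, window13, window14, k = 2) {
  stopifnot(max(window13) < min(window14))
  c13 <- madFilter(poolCentroids(foci, window13), k)
  c14 <- madFilter(poolCentroids(foci, window14), k)
  a13 <- hullArea(c13)
  a14 <- hullArea(c14)
  list(areaNc13 = a13, areaNc14 = a14, deltaArea = a14 - a13,
       nPointsRemoved = attr(c13, "nRemoved") + attr(c14, "nRemoved"))
}
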