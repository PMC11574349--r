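# Shared fixtures: small synthetic configurations and scoring helpers.

# Dense nc14-like field in a cropped 256 px field of view; ~60 nuclei inside
# the ventral sna-like band at spot SNR 10 (amplitude 2000 / noise sd 200).
defaultFociConfig <- function(seed = 0L, perturbation = optoquant::perturbation("none"),
                              nFrames = 100L) {
  simConfig(imageShape = c(256L, 256L), nFrames = nFrames, seed = seed,
            nucleusRadiusUm = 2.2, nucleusSpacingUm = 5,
            perturbation = perturbation,
            noise = list(gaussianSd = 200, poisson = FALSE,
                         saltPepperFraction = 0.001))
}

# Sparse flat field: wide spacing, no gradient, tiny read noise -- isolates
# segmentation/tracking geometry from contrast effects.
flatFieldConfig <- function(seed = 3L, imageShape = c(192L, 192L),
                            nFrames = 2L, nucleusSpacingUm = 8, ...) {
  simConfig(imageShape = imageShape, nFrames = nFrames, seed = seed,
            nucleusSpacingUm = nucleusSpacingUm,
            gradient = list(amplitude = 0, peakPosition = 0.5, sigma = 0.25,
                            offset = 500),
            ...)
}

# Per-frame precision/recall of detections against true spot centroids.
# A detection is correct when it lies within `tol` px of a true site
# (tol = the nuclear radius attributes it to the right nucleus).
scoreDetections <- function(foci, fociTruth, frames, tol) {
  vapply(frames, function(f) {
    det <- foci[foci$frame == f, ]
    tru <- fociTruth[fociTruth$frame == f, ]
    if (nrow(tru) == 0 || nrow(det) == 0) return(c(NA_real_, NA_real_))
    dm <- outer(seq_len(nrow(det)), seq_len(nrow(tru)), function(i, j)
      sqrt((det$y[i] - tru$y[j])^2 + (det$x[i] - tru$x[j])^2))
    c(precision = mean(apply(dm, 1, min) <= tol),
      recall = mean(apply(dm, 2, min) <= tol))
  }, numeric(2))
}

# Fraction of a track's points that belong to its majority true nucleus.
trackPurity <- function(trackSet, nucleiTracks) {
  tr <- trackTable(trackSet)
  vapply(trackIds(trackSet), function(id) {
    d <- tr[tr$track == id, ]
    assigned <- vapply(seq_len(nrow(d)), function(i) {
      tt <- nucleiTracks[nucleiTracks$frame == d$frame[i], ]
      tt$track[which.min((tt$y - d$y[i])^2 + (tt$x - d$x[i])^2)]
    }, numeric(1))
    max(table(assigned)) / length(assigned)
  }, numeric(1))
}

# Circular distance between two positions on the unit circle [0, 1).
circDist <- function(a, b) pmin(abs(a - b) %% 1, 1 - abs(a - b) %% 1)

# Shoelace polygon area over an index cycle (independent oracle for hulls).
shoelace <- function(x, y) {
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
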