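# Readers/writers (multi-page 16-bit TIFF with YAML sidecar metadata, CSV,
# JSON ground truth) and the end-to-end pipeline orchestrator.

#' Write a stack as a multi-page 16-bit grayscale TIFF
#'
#' One page per frame; intensities are rounded and clipped to [0, 65535].
#' Pixel size and frame interval go to a YAML sidecar (`<path>.yaml`), since
#' plain TIFF tags are unreliable across writers.
#'
#' @param stack an [ImageStack-class].
#' @param path output file path (.tif).
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path) {
  pages <- lapply(seq_len(nFrames(stack)), function(t)
    round(pmin(pmax(stackFrame(stack, t), 0), 65535)) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  yaml::write_yaml(list(pixel_size_um = pixelSize(stack),
                        frame_interval_s = frameInterval(stack)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a multi-page grayscale TIFF as an ImageStack
#'
#' Metadata come from the YAML sidecar written by [writeStack()] when
#' present, otherwise from the arguments.
#'
#' @param path TIFF path.
#' @param pixelSizeUm,frameIntervalS calibration overrides; required when no
#'   sidecar exists.
#' @return An [ImageStack-class] with intensities on the 16-bit scale.
#' @export
readStack <- function(path, pixelSizeUm = NULL, frameIntervalS = NULL) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("expected grayscale pages; got RGB or irregular page shapes")
  d <- dim(pages[[1]])
  if (any(vapply(pages, function(p) any(dim(p) != d), logical(1))))
    stop("expected grayscale pages; got RGB or irregular page shapes")
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    if (is.null(pixelSizeUm)) pixelSizeUm <- meta$pixel_size_um
    if (is.null(frameIntervalS)) frameIntervalS <- meta$frame_interval_s
  }
  if (is.null(pixelSizeUm))
    stop("pixel size unknown; supply pixelSizeUm= or a sidecar yaml")
  if (is.null(frameIntervalS))
    stop("frame interval unknown; supply frameIntervalS= or a sidecar yaml")
  data <- array(unlist(pages), c(d[1], d[2], length(pages))) * 65535
  imageStack(data, pixelSizeUm, frameIntervalS)
}

.writeCsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write ground truth as JSON
#' @param truth a generator truth list.
#' @param path output path.
#' @export
writeGroundTruth <- function(truth, path) {
  truth$embryoMask <- NULL   # rasters do not belong in JSON
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the simulate -> detect -> count -> area pipeline
#'
#' Simulates a focus movie from `config`, detects foci, writes the per-frame
#' centroid table, the count series, the nc13/nc14 area summary and a run
#' log. All artifacts are deterministic under the config seed.
#'
#' @param config a [SimConfig-class].
#' @param outDir output directory (created if needed).
#' @param fociPar a [fociParams()] list.
#' @param window13,window14 frame windows for the area difference; defaults
#'   split the movie in half.
#' @return Invisibly, a list with the in-memory results.
#' @export
runPipeline <- function(config, outDir, fociPar = fociParams(),
                        window13 = NULL, window14 = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  sim <- simulateFociMovie(config)
  writeStack(sim$stack, file.path(outDir, "movie.tif"))
  foci <- detectFoci(sim$stack, fociPar, nNc14Frames = config@nFrames)
  .writeCsv(foci, file.path(outDir, "foci.csv"))
  series <- countSeries(foci, config@nFrames, config@frameIntervalS)
  .writeCsv(series, file.path(outDir, "count_series.csv"))
  if (is.null(window13)) window13 <- seq_len(floor(config@nFrames / 2))
  if (is.null(window14)) window14 <- (floor(config@nFrames / 2) + 1):config@nFrames
  area <- deltaArea(foci, window13, window14)
  jsonlite::write_json(area, file.path(outDir, "area.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- list(started = format(t0), finished = format(Sys.time()),
              seed = config@seed,
              version = as.character(utils::packageVersion("optoquant")),
              fociParams = fociPar,
              nFrames = config@nFrames, imageShape = config@imageShape)
  jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                       auto_unbox = TRUE)
  invisible(list(foci = foci, series = series, area = area))
}

#' Write a QC overlay of detected foci
#'
#' Writes a PNG of one frame with detected foci circled, the static
#' counterpart of overlaying the segmentation mask on the image to judge a
#' threshold choice.
#'
#' @param image Y x X matrix.
#' @param foci data.frame with y, x columns (one frame's detections).
#' @param path output PNG path.
#' @param radius circle radius in px.
#' @return `path`, invisibly.
#' @export
writeFociOverlay <- function(image, foci, path, radius = 4) {
  g <- pmin(pmax(image / max(image, 1), 0), 1)
  rgb <- array(rep(g, 3), c(dim(g), 3))
  th <- seq(0, 2 * pi, length.out = 64)
  for (i in seq_len(nrow(foci))) {
    cy <- round(foci$y[i] + radius * sin(th))
    cx <- round(foci$x[i] + radius * cos(th))
    ok <- cy >= 1 & cy <= nrow(g) & cx >= 1 & cx <= ncol(g)
    rgb[cbind(cy[ok], cx[ok], 1)] <- 1
    rgb[cbind(cy[ok], cx[ok], 2)] <- 0
    rgb[cbind(cy[ok], cx[ok], 3)] <- 0
  }
  png::writePNG(rgb, path)
  invisible(path)
}
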