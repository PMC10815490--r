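# Mapping stage: video frames -> silhouette -> per-column diameter ->
# calibrated spatiotemporal diameter map.

#' Threshold a frame into a tissue silhouette
#'
#' Edge detection by intensity thresholding: the frame is converted into
#' a binary silhouette in which TRUE marks tissue. The threshold is
#' either found automatically by Otsu's method (per frame) or supplied.
#'
#' @param frame numeric matrix of intensities.
#' @param method \code{"otsu"} (default) or \code{"fixed"}.
#' @param threshold required when \code{method = "fixed"}; ignored for
#'   Otsu.
#' @param polarity \code{"tissue_bright"} (tissue above threshold,
#'   default: organ-bath tissue is lit from above and brighter than the
#'   bath floor) or \code{"tissue_dark"}.
#' @return logical matrix of the same shape as \code{frame}.
#' @details A constant-intensity frame has no separable intensity
#'   classes and is rejected under Otsu.
#' @examples
#' f <- matrix(20, 10, 10); f[3:7, ] <- 200
#' mask <- silhouetteMask(f)
#' colSums(mask)
#' @export
silhouetteMask <- function(frame, method = c("otsu", "fixed"),
                           threshold = NULL,
                           polarity = c("tissue_bright", "tissue_dark")) {
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  if (!is.matrix(frame) || !is.numeric(frame) || length(frame) == 0L)
    stop("frame must be a non-empty numeric matrix")
  if (method == "otsu") {
    rg <- range(frame)
    if (diff(rg) == 0)
      stop("no separable classes: frame intensity is constant")
    th <- EBImage::otsu(EBImage::Image(frame), range = rg, levels = 256L)
  } else {
    if (is.null(threshold))
      stop("threshold is required when method = \"fixed\"")
    th <- threshold
  }
  if (polarity == "tissue_bright") frame > th else frame <= th
}

#' Per-column diameter profile from a silhouette
#'
#' The diameter under each horizontal (column) position is the count of
#' silhouette pixels in that column times the calibration. Counting -
#' rather than top-minus-bottom extent - is deliberate: interior holes
#' in the silhouette reduce the measured diameter.
#'
#' @param mask logical matrix (tissue silhouette).
#' @param calibration mm per pixel (> 0).
#' @return numeric vector, mm, one entry per column of \code{mask}.
#' @examples
#' m <- matrix(FALSE, 60, 5); m[1:47, ] <- TRUE
#' diameterProfile(m, 0.1)   # 4.7 mm everywhere
#' @export
diameterProfile <- function(mask, calibration) {
  if (!is.numeric(calibration) || length(calibration) != 1L ||
      calibration <= 0)
    stop("calibration must be a single positive number (mm/px)")
  colSums(mask) * calibration
}

#' Build a spatiotemporal diameter map from a frame stack
#'
#' Each frame is thresholded into a silhouette, per-column diameters are
#' counted, and the resulting (position, time) matrix is optionally
#' block-averaged in space and time. Block means (not decimation) act as
#' an anti-aliasing filter ahead of any spectral analysis.
#'
#' @param stack a [FrameStack-class].
#' @param downsampleTime,downsampleSpace integer block sizes (>= 1);
#'   trailing samples that do not fill a block are truncated.
#' @inheritParams silhouetteMask
#' @param flip set TRUE when the video is filmed anal-end-left, so that
#'   row 1 of the map is always the oral end.
#' @return A [SpatioTemporalMap-class] with
#'   \code{spatialStep = columnSpacing * downsampleSpace} (column
#'   spacing equals the calibration for square-pixel video) and
#'   \code{temporalStep = downsampleTime / frameRate}.
#' @examples
#' sc <- MotilityScenario(duration = 5, slowWaveAmplitude = 0, seed = 1)
#' stack <- renderFrames(simulateMap(sc)$map, calibration = 0.1)
#' buildMap(stack)
#' @export
buildMap <- function(stack, downsampleTime = 1L, downsampleSpace = 1L,
                     method = c("otsu", "fixed"), threshold = NULL,
                     polarity = c("tissue_bright", "tissue_dark"),
                     flip = FALSE) {
  stopifnot(is(stack, "FrameStack"))
  nt <- nFrames(stack)
  if (nt == 0L) stop("empty frame stack")
  downsampleTime <- as.integer(downsampleTime)
  downsampleSpace <- as.integer(downsampleSpace)
  if (downsampleTime < 1L || downsampleSpace < 1L)
    stop("downsampling factors must be integers >= 1")
  method <- match.arg(method)
  polarity <- match.arg(polarity)
  prof <- vapply(seq_len(nt), function(i) {
    diameterProfile(
      silhouetteMask(getFrame(stack, i), method, threshold, polarity),
      calibration(stack))
  }, numeric(dim(stack@frames)[3]))            # positions x time
  if (flip) prof <- prof[rev(seq_len(nrow(prof))), , drop = FALSE]
  blockMean <- function(m, fRow, fCol) {
    nr <- (nrow(m) %/% fRow) * fRow
    nc <- (ncol(m) %/% fCol) * fCol
    m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
    if (fRow > 1L) {
      m <- apply(array(m, dim = c(fRow, nr %/% fRow, nc)), c(2, 3),
                 mean)
    }
    if (fCol > 1L) {
      m <- t(apply(array(t(m), dim = c(fCol, nc %/% fCol, nrow(m))),
                   c(2, 3), mean))
    }
    m
  }
  d <- blockMean(prof, downsampleSpace, downsampleTime)
  SpatioTemporalMap(d,
                    spatialStep = stack@columnSpacing * downsampleSpace,
                    temporalStep = downsampleTime / frameRate(stack))
}

#' Write / read a spatiotemporal map as delimited text plus JSON sidecar
#'
#' The matrix is written as tab-delimited text (rows = positions oral to
#' anal, columns = time samples) at full precision, with a JSON sidecar
#' (same path with extension \code{.json}) recording
#' \code{spatial_step}, \code{temporal_step}, \code{units},
#' \code{orientation}, \code{n_positions} and \code{n_times}. A
#' write-read round trip reproduces the map exactly.
#'
#' @param map a [SpatioTemporalMap-class].
#' @param path path of the matrix file; the sidecar path is derived by
#'   replacing / adding the \code{.json} extension.
#' @return \code{writeMap} returns \code{path} invisibly;
#'   \code{readMap} returns the map.
#' @export
writeMap <- function(map, path) {
  stopifnot(is(map, "SpatioTemporalMap"))
  utils::write.table(
    format(diameterMatrix(map), digits = 17, trim = TRUE,
           scientific = TRUE),
    path, sep = "\t", row.names = FALSE, col.names = FALSE,
    quote = FALSE)
  sidecar <- list(spatial_step = spatialStep(map),
                  temporal_step = temporalStep(map),
                  units = "mm",
                  orientation = "oral_to_anal",
                  n_positions = nrow(diameterMatrix(map)),
                  n_times = ncol(diameterMatrix(map)))
  jsonlite::write_json(sidecar, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecarPath <- function(path) paste0(sub("\\.[^./\\\\]*$", "", path), ".json")

#' @rdname writeMap
#' @export
readMap <- function(path) {
  sp <- sidecarPath(path)
  if (!file.exists(sp))
    stop("missing JSON sidecar for map file: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  need <- c("spatial_step", "temporal_step", "n_positions", "n_times")
  missing <- setdiff(need, names(meta))
  if (length(missing))
    stop("sidecar is missing required fields: ",
         paste(missing, collapse = ", "))
  d <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(d) <- NULL
  if (nrow(d) != meta$n_positions || ncol(d) != meta$n_times)
    stop("matrix is ", nrow(d), " x ", ncol(d),
         " but sidecar declares ", meta$n_positions, " x ", meta$n_times)
  SpatioTemporalMap(d, meta$spatial_step, meta$temporal_step)
}

#' Write / read a frame stack as a multi-page TIFF
#'
#' Intensities are stored as 16-bit grayscale in \[0, 1\]. Frame rate and
#' calibration are not part of the TIFF payload and must be re-supplied
#' on read (they travel in recording metadata, not pixels).
#'
#' @param stack a [FrameStack-class].
#' @param path TIFF file path.
#' @param frameRate,calibration,columnSpacing metadata for the stack
#'   being read.
#' @return \code{writeFrameStack} returns \code{path} invisibly;
#'   \code{readFrameStack} returns a [FrameStack-class].
#' @export
writeFrameStack <- function(stack, path) {
  stopifnot(is(stack, "FrameStack"))
  pages <- lapply(seq_len(nFrames(stack)), function(i) getFrame(stack, i))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeFrameStack
#' @export
readFrameStack <- function(path, frameRate, calibration,
                           columnSpacing = calibration) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  frames <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) frames[i, , ] <- pages[[i]]
  FrameStack(frames, frameRate, calibration, columnSpacing)
}
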