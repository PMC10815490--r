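#' @rdname SpatioTemporalMap-class
#' @param object,x a SpatioTemporalMap
#' @export
setGeneric("diameterMatrix", function(x) standardGeneric("diameterMatrix"))

#' @rdname SpatioTemporalMap-class
#' @export
setMethod("diameterMatrix", "SpatioTemporalMap", function(x) x@diameter)

#' @rdname SpatioTemporalMap-class
#' @export
setGeneric("spatialStep", function(x) standardGeneric("spatialStep"))

#' @rdname SpatioTemporalMap-class
#' @export
setMethod("spatialStep", "SpatioTemporalMap", function(x) x@spatialStep)

#' @rdname SpatioTemporalMap-class
#' @export
setGeneric("temporalStep", function(x) standardGeneric("temporalStep"))

#' @rdname SpatioTemporalMap-class
#' @export
setMethod("temporalStep", "SpatioTemporalMap", function(x) x@temporalStep)

#' @rdname SpatioTemporalMap-class
#' @export
setGeneric("segmentLength", function(x) standardGeneric("segmentLength"))

#' @rdname SpatioTemporalMap-class
#' @export
setMethod("segmentLength", "SpatioTemporalMap", function(x)
  (nrow(x@diameter) - 1L) * x@spatialStep)

#' @rdname SpatioTemporalMap-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname SpatioTemporalMap-class
#' @export
setMethod("positions", "SpatioTemporalMap", function(x)
  (seq_len(nrow(x@diameter)) - 1) * x@spatialStep)

#' @rdname SpatioTemporalMap-class
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname SpatioTemporalMap-class
#' @export
setMethod("timePoints", "SpatioTemporalMap", function(x)
  (seq_len(ncol(x@diameter)) - 1) * x@temporalStep)

#' @rdname SpatioTemporalMap-class
#' @export
setMethod("dim", "SpatioTemporalMap", function(x) dim(x@diameter))

setMethod("show", "SpatioTemporalMap", function(object) {
  d <- dim(object@diameter)
  cat("SpatioTemporalMap:", d[1], "positions x", d[2], "time samples\n")
  cat(sprintf("  segment %.1f mm (step %.3g mm), duration %.1f s (step %.3g s)\n",
              segmentLength(object), object@spatialStep,
              (d[2] - 1) * object@temporalStep, object@temporalStep))
  cat(sprintf("  diameter range %.2f-%.2f mm\n",
              min(object@diameter), max(object@diameter)))
})

#' @rdname FrameStack-class
#' @param x a FrameStack
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname FrameStack-class
#' @export
setMethod("frameRate", "FrameStack", function(x) x@frameRate)

#' @rdname FrameStack-class
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))

#' @rdname FrameStack-class
#' @export
setMethod("calibration", "FrameStack", function(x) x@calibration)

#' @rdname FrameStack-class
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname FrameStack-class
#' @export
setMethod("nFrames", "FrameStack", function(x) dim(x@frames)[1])

#' @rdname FrameStack-class
#' @param i frame index
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname FrameStack-class
#' @export
setMethod("getFrame", "FrameStack", function(x, i)
  x@frames[i, , , drop = TRUE])

#' @rdname FrameStack-class
#' @export
setGeneric("columnSpacing", function(x) standardGeneric("columnSpacing"))

#' @rdname FrameStack-class
#' @export
setMethod("columnSpacing", "FrameStack", function(x) x@columnSpacing)

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat("FrameStack:", d[1], "frames of", d[2], "x", d[3], "px\n")
  cat(sprintf("  %.3g Hz, %.3g mm/px (field %.1f x %.1f mm)\n",
              object@frameRate, object@calibration,
              d[2] * object@calibration, d[3] * object@columnSpacing))
})

#' @rdname WidthTrace-class
#' @param x a WidthTrace
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' @rdname WidthTrace-class
#' @export
setMethod("traceValues", "WidthTrace", function(x) x@values)

#' @rdname WidthTrace-class
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))

#' @rdname WidthTrace-class
#' @export
setMethod("traceTimes", "WidthTrace", function(x) x@times)

#' @rdname WidthTrace-class
#' @export
setGeneric("restingDiameter", function(x) standardGeneric("restingDiameter"))

#' @rdname WidthTrace-class
#' @export
setMethod("restingDiameter", "WidthTrace", function(x) x@restingDiameter)

#' @rdname WidthTrace-class
#' @export
setGeneric("constrictedDiameter",
           function(x) standardGeneric("constrictedDiameter"))

#' @rdname WidthTrace-class
#' @export
setMethod("constrictedDiameter", "WidthTrace",
          function(x) x@constrictedDiameter)

setMethod("show", "WidthTrace", function(object) {
  cat(sprintf("WidthTrace at %.1f mm: %d samples\n", object@position,
              length(object@values)))
  cat(sprintf("  resting %.2f mm, constricted %.2f mm\n",
              object@restingDiameter, object@constrictedDiameter))
})

#' @rdname Spectrum-class
#' @param x a Spectrum
#' @export
setGeneric("dominantFrequency",
           function(x) standardGeneric("dominantFrequency"))

#' @rdname Spectrum-class
#' @export
setMethod("dominantFrequency", "Spectrum", function(x) x@dominantFrequency)

#' @rdname Spectrum-class
#' @export
setGeneric("spectralResolution",
           function(x) standardGeneric("spectralResolution"))

#' @rdname Spectrum-class
#' @export
setMethod("spectralResolution", "Spectrum", function(x) x@resolution)

setMethod("show", "Spectrum", function(object) {
  cat(sprintf(
    "Spectrum: dominant %.4g 1/s in band [%.3g, %.3g] (resolution %.2g 1/s)\n",
    object@dominantFrequency, object@searchBand[1], object@searchBand[2],
    object@resolution))
})

setMethod("show", "ColonSummary", function(object) {
  cat("ColonSummary\n")
  cat(sprintf("  CMMCs / window: %d (mean length %.1f mm)\n",
              object@cmmcPer15min, object@cmmcLength))
  cat(sprintf("  resting diameter: %.2f mm\n", object@restingDiameter))
  cat(sprintf("  short anal contractions / window: %d (%.1f%% of total)\n",
              object@shortAnalPer15min, object@shortFraction))
})

setMethod("show", "MotilityScenario", function(object) {
  cat(sprintf(
    "MotilityScenario: %.0f mm x %.0f s, resting %.1f mm, %d events, seed %d\n",
    object@segmentLength, object@duration, object@restingDiameter,
    nrow(object@events), object@seed))
})
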