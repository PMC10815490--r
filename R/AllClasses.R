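#' @import methods
NULL

#' SpatioTemporalMap: gut diameter by position and time
#'
#' The central container of the package: a matrix of gut diameter (mm)
#' indexed by position along the segment (rows, oral end at row 1,
#' increasing towards the anal end) and by time (columns). It is the
#' object a heatmap of motility is drawn from, and the input to all
#' contraction-detection machinery.
#'
#' @slot diameter numeric matrix of diameters in mm, rows = positions
#'   (oral to anal), columns = time samples.
#' @slot spatialStep distance between adjacent rows, mm.
#' @slot temporalStep time between adjacent columns, s.
#'
#' @details Positions are \code{(i - 1) * spatialStep} mm from the oral
#'   end; times are \code{(j - 1) * temporalStep} s from the start of the
#'   recording. The segment length is \code{(nrow - 1) * spatialStep}.
#'
#' @seealso [SpatioTemporalMap()] for the constructor,
#'   [buildMap()] to derive one from a [FrameStack-class],
#'   [simulateMap()] to generate one synthetically.
#' @name SpatioTemporalMap-class
#' @aliases SpatioTemporalMap-class
#' @exportClass SpatioTemporalMap
setClass("SpatioTemporalMap",
  representation(
    diameter     = "matrix",
    spatialStep  = "numeric",
    temporalStep = "numeric"
  )
)

setValidity("SpatioTemporalMap", function(object) {
  msg <- character()
  d <- object@diameter
  if (!is.numeric(d) || nrow(d) < 2L || ncol(d) < 1L)
    msg <- c(msg, "diameter must be a numeric matrix with >= 2 positions")
  if (any(!is.finite(d)))
    msg <- c(msg, "diameter contains non-finite values")
  else if (any(d < 0))
    msg <- c(msg, "diameters must be >= 0")
  if (length(object@spatialStep) != 1L || object@spatialStep <= 0)
    msg <- c(msg, "spatialStep must be a single positive number (mm)")
  if (length(object@temporalStep) != 1L || object@temporalStep <= 0)
    msg <- c(msg, "temporalStep must be a single positive number (s)")
  if (length(msg)) msg else TRUE
})

#' FrameStack: a time-ordered stack of grayscale video frames
#'
#' Raw material of the mapping stage: grayscale frames of a gut segment
#' filmed from above in an organ bath, with the frame rate and the
#' pixel-to-mm calibration needed to turn silhouettes into diameters.
#'
#' @slot frames numeric array (time, row, column) of intensities.
#' @slot frameRate frames per second (Hz).
#' @slot calibration mm per pixel along the diameter (vertical) axis.
#' @slot columnSpacing mm between adjacent pixel columns along the
#'   segment; equals \code{calibration} for real video (square pixels)
#'   but may differ for synthetic stacks rendered from a map sampled on
#'   its own spatial grid.
#'
#' @seealso [FrameStack()], [buildMap()], [renderFrames()]
#' @name FrameStack-class
#' @aliases FrameStack-class
#' @exportClass FrameStack
setClass("FrameStack",
  representation(
    frames        = "array",
    frameRate     = "numeric",
    calibration   = "numeric",
    columnSpacing = "numeric"
  )
)

setValidity("FrameStack", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "frames must be a 3-d array (time, row, column)")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number (Hz)")
  if (length(object@calibration) != 1L || object@calibration <= 0)
    msg <- c(msg, "calibration must be a single positive number (mm/px)")
  if (length(object@columnSpacing) != 1L || object@columnSpacing <= 0)
    msg <- c(msg, "columnSpacing must be a single positive number (mm)")
  if (length(msg)) msg else TRUE
})

#' MotilityScenario: ground-truth description of a simulated recording
#'
#' A declarative description of an ex vivo recording used by
#' [simulateMap()]: a resting tube of tissue with a superimposed
#' slow-wave oscillation, a schedule of propagating constriction events,
#' and additive measurement noise.
#'
#' @slot segmentLength segment length, mm.
#' @slot duration recording duration, s.
#' @slot restingDiameter baseline diameter, mm.
#' @slot slowWaveAmplitude amplitude of the sinusoidal slow-wave
#'   component, mm (0 disables it).
#' @slot slowWaveFrequency slow-wave frequency, s^-1.
#' @slot events data.frame with one row per scheduled event; columns
#'   \code{onset_time} (s), \code{origin_position} (mm),
#'   \code{extent_fraction} (of segment length, in (0, 1]),
#'   \code{velocity} (mm/s, signed, positive = oral-to-anal),
#'   \code{dwell} (s, full width at half depth of the constriction at a
#'   fixed position), \code{depth_fraction} (fraction of resting diameter
#'   removed at peak, in (0, 1)).
#' @slot noiseSd additive Gaussian noise SD on diameter, mm.
#' @slot spatialStep map row spacing, mm.
#' @slot temporalStep map column spacing, s.
#' @slot seed integer RNG seed; mandatory so every simulation is
#'   reproducible.
#'
#' @seealso [MotilityScenario()], [simulateMap()]
#' @name MotilityScenario-class
#' @aliases MotilityScenario-class
#' @exportClass MotilityScenario
setClass("MotilityScenario",
  representation(
    segmentLength     = "numeric",
    duration          = "numeric",
    restingDiameter   = "numeric",
    slowWaveAmplitude = "numeric",
    slowWaveFrequency = "numeric",
    events            = "data.frame",
    noiseSd           = "numeric",
    spatialStep       = "numeric",
    temporalStep      = "numeric",
    seed              = "integer"
  )
)

.eventCols <- c("onset_time", "origin_position", "extent_fraction",
                "velocity", "dwell", "depth_fraction")

setValidity("MotilityScenario", function(object) {
  msg <- character()
  scal <- function(x) length(x) == 1L && is.finite(x)
  if (!scal(object@segmentLength) || object@segmentLength <= 0)
    msg <- c(msg, "segmentLength must be > 0")
  if (!scal(object@duration) || object@duration <= 0)
    msg <- c(msg, "duration must be > 0")
  if (!scal(object@restingDiameter) || object@restingDiameter <= 0)
    msg <- c(msg, "restingDiameter must be > 0")
  if (!scal(object@slowWaveAmplitude) || object@slowWaveAmplitude < 0 ||
      object@slowWaveAmplitude >= object@restingDiameter)
    msg <- c(msg, "slowWaveAmplitude must satisfy 0 <= amplitude < restingDiameter")
  if (!scal(object@slowWaveFrequency) || object@slowWaveFrequency < 0)
    msg <- c(msg, "slowWaveFrequency must be >= 0")
  if (!scal(object@noiseSd) || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (!scal(object@spatialStep) || object@spatialStep <= 0)
    msg <- c(msg, "spatialStep must be > 0")
  if (!scal(object@temporalStep) || object@temporalStep <= 0)
    msg <- c(msg, "temporalStep must be > 0")
  if (object@slowWaveFrequency > 0 && scal(object@temporalStep) &&
      object@temporalStep > 1 / (2 * object@slowWaveFrequency))
    msg <- c(msg, "temporalStep violates Nyquist for slowWaveFrequency")
  ev <- object@events
  if (!all(.eventCols %in% names(ev))) {
    msg <- c(msg, paste("events must have columns:",
                        paste(.eventCols, collapse = ", ")))
  } else if (nrow(ev)) {
    if (any(ev$onset_time < 0)) msg <- c(msg, "event onset_time must be >= 0")
    if (any(ev$extent_fraction <= 0 | ev$extent_fraction > 1))
      msg <- c(msg, "event extent_fraction must lie in (0, 1]")
    if (any(ev$dwell <= 0)) msg <- c(msg, "event dwell must be > 0")
    if (any(ev$depth_fraction <= 0 | ev$depth_fraction >= 1))
      msg <- c(msg, "event depth_fraction must lie in (0, 1)")
    if (any(ev$velocity == 0))
      msg <- c(msg, "event velocity must be nonzero")
  }
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' TransitScenario: a simulated radiographic transit study
#'
#' Describes per-group distributions of the three transit components:
#' small-intestinal transit (gavage to caecum), caecal dwell (caecum to
#' proximal colon) and colonic transit (proximal colon to first pellet).
#' The caecal dwell is explicit so that whole transit exceeds the sum of
#' small-intestinal and colonic transit, as observed group means require.
#'
#' @slot nPerGroup animals per group.
#' @slot meanSitt named numeric, group mean small-intestinal transit, min.
#' @slot meanCaecalDwell named numeric, group mean caecal dwell, min.
#' @slot meanCtt named numeric, group mean colonic transit, min.
#' @slot dispersion SD of each component, min.
#' @slot pelletFailureProbability probability an animal never produces a
#'   contrast-containing pellet and is excluded.
#' @slot seed integer RNG seed.
#'
#' @seealso [TransitScenario()], [simulateTransitCohort()]
#' @name TransitScenario-class
#' @aliases TransitScenario-class
#' @exportClass TransitScenario
setClass("TransitScenario",
  representation(
    nPerGroup                = "integer",
    meanSitt                 = "numeric",
    meanCaecalDwell          = "numeric",
    meanCtt                  = "numeric",
    dispersion               = "numeric",
    pelletFailureProbability = "numeric",
    seed                     = "integer"
  )
)

setValidity("TransitScenario", function(object) {
  msg <- character()
  g <- names(object@meanSitt)
  if (is.null(g) || any(!nzchar(g)))
    msg <- c(msg, "meanSitt must be a named vector (one entry per group)")
  if (!identical(names(object@meanCaecalDwell), g) ||
      !identical(names(object@meanCtt), g))
    msg <- c(msg, "meanSitt, meanCaecalDwell, meanCtt must share group names")
  if (any(c(object@meanSitt, object@meanCaecalDwell, object@meanCtt) <= 0))
    msg <- c(msg, "all component means must be > 0")
  if (length(object@nPerGroup) != 1L || object@nPerGroup < 1L)
    msg <- c(msg, "nPerGroup must be a positive integer")
  if (length(object@dispersion) != 1L || object@dispersion < 0)
    msg <- c(msg, "dispersion must be >= 0")
  p <- object@pelletFailureProbability
  if (length(p) != 1L || p < 0 || p >= 1)
    msg <- c(msg, "pelletFailureProbability must lie in [0, 1)")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' LengthScenario: a simulated paired gut-length study
#'
#' Emulates measuring small-intestinal length before and after incubation
#' in a smooth-muscle relaxant: the relaxed length is common to all
#' groups, active smooth-muscle tone shortens it by a group-specific
#' amount, and the relaxant leaves only a small residual tone.
#'
#' @slot nPerGroup animals per group.
#' @slot relaxedLengthMean fully relaxed length, cm.
#' @slot toneShortening named numeric, cm of shortening due to tone per
#'   group under control conditions.
#' @slot nicardipineResidualTone residual shortening under the relaxant,
#'   cm (common to groups).
#' @slot sd between-animal SD, cm.
#' @slot seed integer RNG seed.
#'
#' @seealso [LengthScenario()], [simulateLengthCohort()]
#' @name LengthScenario-class
#' @aliases LengthScenario-class
#' @exportClass LengthScenario
setClass("LengthScenario",
  representation(
    nPerGroup               = "integer",
    relaxedLengthMean       = "numeric",
    toneShortening          = "numeric",
    nicardipineResidualTone = "numeric",
    sd                      = "numeric",
    seed                    = "integer"
  )
)

setValidity("LengthScenario", function(object) {
  msg <- character()
  if (is.null(names(object@toneShortening)) ||
      any(!nzchar(names(object@toneShortening))))
    msg <- c(msg, "toneShortening must be a named vector (one entry per group)")
  if (any(object@toneShortening < 0))
    msg <- c(msg, "toneShortening must be >= 0")
  if (any(object@relaxedLengthMean <= object@toneShortening))
    msg <- c(msg, "relaxedLengthMean must exceed every toneShortening")
  if (length(object@nicardipineResidualTone) != 1L ||
      object@nicardipineResidualTone < 0)
    msg <- c(msg, "nicardipineResidualTone must be >= 0")
  if (length(object@sd) != 1L || object@sd < 0)
    msg <- c(msg, "sd must be >= 0")
  if (length(object@nPerGroup) != 1L || object@nPerGroup < 1L)
    msg <- c(msg, "nPerGroup must be a positive integer")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' WidthTrace: gut width against time at a fixed position
#'
#' A cross-section of a [SpatioTemporalMap-class] at one position, with
#' its envelope summarized as resting (upper) and constricted (lower)
#' diameter.
#'
#' @slot position position along the segment, mm from the oral end.
#' @slot times time samples, s.
#' @slot values diameter at each time, mm.
#' @slot restingDiameter upper-envelope diameter, mm.
#' @slot constrictedDiameter lower-envelope diameter, mm.
#'
#' @seealso [widthTrace()], [restingConstricted()], [intraPccFrequency()]
#' @name WidthTrace-class
#' @aliases WidthTrace-class
#' @exportClass WidthTrace
setClass("WidthTrace",
  representation(
    position            = "numeric",
    times               = "numeric",
    values              = "numeric",
    restingDiameter     = "numeric",
    constrictedDiameter = "numeric"
  )
)

setValidity("WidthTrace", function(object) {
  msg <- character()
  if (length(object@values) != length(object@times))
    msg <- c(msg, "times and values must have equal length")
  if (any(object@values < 0))
    msg <- c(msg, "diameters must be >= 0")
  if (object@constrictedDiameter > object@restingDiameter)
    msg <- c(msg, "constrictedDiameter must be <= restingDiameter")
  if (length(msg)) msg else TRUE
})

#' Spectrum: a one-sided power spectrum of a width trace
#'
#' @slot frequencies frequency grid, s^-1.
#' @slot power spectral power, arbitrary units.
#' @slot dominantFrequency argmax of power within the search band, s^-1.
#' @slot searchBand two-element numeric (lo, hi), s^-1.
#' @slot resolution spectral resolution (bin width), s^-1.
#'
#' @seealso [intraPccFrequency()]
#' @name Spectrum-class
#' @aliases Spectrum-class
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    frequencies       = "numeric",
    power             = "numeric",
    dominantFrequency = "numeric",
    searchBand        = "numeric",
    resolution        = "numeric"
  )
)

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@frequencies) != length(object@power))
    msg <- c(msg, "frequencies and power must have equal length")
  if (any(object@power < 0)) msg <- c(msg, "power must be >= 0")
  if (length(object@searchBand) != 2L ||
      object@searchBand[1] >= object@searchBand[2])
    msg <- c(msg, "searchBand must be (lo, hi) with lo < hi")
  if (object@dominantFrequency < object@searchBand[1] ||
      object@dominantFrequency > object@searchBand[2])
    msg <- c(msg, "dominantFrequency must lie within searchBand")
  if (length(msg)) msg else TRUE
})

#' ColonSummary: colonic motility metrics for one recording
#'
#' @slot cmmcPer15min number of colonic migrating motor complexes in the
#'   analysis window.
#' @slot cmmcLength mean spatial extent of CMMCs, mm (NA if none).
#' @slot restingDiameter mid-colon resting diameter, mm.
#' @slot shortAnalPer15min number of short anal contractions.
#' @slot shortFraction short contractions as a percentage of total
#'   contractions (NA when no contraction was detected).
#'
#' @seealso [cmmcMetrics()], [shortAnalContractions()]
#' @name ColonSummary-class
#' @aliases ColonSummary-class
#' @exportClass ColonSummary
setClass("ColonSummary",
  representation(
    cmmcPer15min      = "numeric",
    cmmcLength        = "numeric",
    restingDiameter   = "numeric",
    shortAnalPer15min = "numeric",
    shortFraction     = "numeric"
  )
)

setValidity("ColonSummary", function(object) {
  msg <- character()
  if (object@cmmcPer15min < 0 || object@shortAnalPer15min < 0)
    msg <- c(msg, "counts must be >= 0")
  sf <- object@shortFraction
  if (!is.na(sf) && (sf < 0 || sf > 100))
    msg <- c(msg, "shortFraction must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})
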