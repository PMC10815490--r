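#' Construct a SpatioTemporalMap
#'
#' @param diameter numeric matrix of diameters (mm), rows = positions
#'   oral to anal, columns = time samples.
#' @param spatialStep row spacing, mm.
#' @param temporalStep column spacing, s.
#' @return A [SpatioTemporalMap-class] object.
#' @examples
#' m <- SpatioTemporalMap(matrix(4.7, 61, 100), spatialStep = 1,
#'                        temporalStep = 0.2)
#' segmentLength(m)
#' @export
SpatioTemporalMap <- function(diameter, spatialStep, temporalStep) {
  new("SpatioTemporalMap", diameter = unname(as.matrix(diameter)),
      spatialStep = as.numeric(spatialStep),
      temporalStep = as.numeric(temporalStep))
}

#' Construct a FrameStack
#'
#' @param frames 3-d numeric array (time, row, column) of intensities.
#' @param frameRate frames per second, Hz.
#' @param calibration mm per pixel along the diameter axis.
#' @param columnSpacing mm between pixel columns; defaults to
#'   \code{calibration} (square pixels).
#' @return A [FrameStack-class] object.
#' @export
FrameStack <- function(frames, frameRate, calibration,
                       columnSpacing = calibration) {
  new("FrameStack", frames = frames, frameRate = as.numeric(frameRate),
      calibration = as.numeric(calibration),
      columnSpacing = as.numeric(columnSpacing))
}

#' Construct a MotilityScenario
#'
#' Defaults describe a 15-min recording of a ~6 cm jejunal segment:
#' resting diameter a few mm, slow-wave oscillation around 0.5 s^-1, map
#' sampled at 1 mm and 0.2 s.
#'
#' @param segmentLength segment length, mm.
#' @param duration recording duration, s.
#' @param restingDiameter baseline diameter, mm.
#' @param slowWaveAmplitude slow-wave amplitude, mm.
#' @param slowWaveFrequency slow-wave frequency, s^-1.
#' @param events data.frame of scheduled events (see
#'   [MotilityScenario-class]); [eventSpec()] builds rows.
#' @param noiseSd additive Gaussian noise SD, mm.
#' @param spatialStep map row spacing, mm.
#' @param temporalStep map column spacing, s.
#' @param seed integer RNG seed (mandatory, not ambient state).
#' @return A [MotilityScenario-class] object.
#' @examples
#' sc <- MotilityScenario(events = eventSpec(onset_time = 100,
#'   origin_position = 0, extent_fraction = 1, velocity = 0.5,
#'   dwell = 30, depth_fraction = 0.5), seed = 1)
#' @export
MotilityScenario <- function(segmentLength = 60, duration = 900,
                             restingDiameter = 4.7,
                             slowWaveAmplitude = 0.25,
                             slowWaveFrequency = 0.5,
                             events = eventSpec(), noiseSd = 0,
                             spatialStep = 1, temporalStep = 0.2,
                             seed) {
  if (missing(seed)) stop("a seed is required for every scenario")
  new("MotilityScenario", segmentLength = as.numeric(segmentLength),
      duration = as.numeric(duration),
      restingDiameter = as.numeric(restingDiameter),
      slowWaveAmplitude = as.numeric(slowWaveAmplitude),
      slowWaveFrequency = as.numeric(slowWaveFrequency),
      events = as.data.frame(events), noiseSd = as.numeric(noiseSd),
      spatialStep = as.numeric(spatialStep),
      temporalStep = as.numeric(temporalStep), seed = as.integer(seed))
}

#' Build an event schedule for a MotilityScenario
#'
#' Each argument is recycled to the length of the longest; calling with
#' no arguments yields an empty schedule. \code{onset_time} is the time
#' the half-depth front of the constriction arrives at
#' \code{origin_position}; \code{dwell} is the full width at half depth
#' of the constriction at a fixed position.
#'
#' @param onset_time s.
#' @param origin_position mm from the oral end.
#' @param extent_fraction fraction of segment length travelled, (0, 1].
#' @param velocity mm/s, signed; positive propagates oral to anal.
#' @param dwell s.
#' @param depth_fraction fraction of resting diameter removed at peak.
#' @return data.frame with one row per event.
#' @export
eventSpec <- function(onset_time = numeric(), origin_position = numeric(),
                      extent_fraction = numeric(), velocity = numeric(),
                      dwell = numeric(), depth_fraction = numeric()) {
  data.frame(onset_time = onset_time, origin_position = origin_position,
             extent_fraction = extent_fraction, velocity = velocity,
             dwell = dwell, depth_fraction = depth_fraction)
}

#' Construct a TransitScenario
#'
#' @param nPerGroup animals per group.
#' @param meanSitt named numeric of group mean small-intestinal transit
#'   times, min.
#' @param meanCaecalDwell named numeric of group mean caecal dwell, min.
#' @param meanCtt named numeric of group mean colonic transit, min.
#' @param dispersion SD of each transit component, min.
#' @param pelletFailureProbability probability a record is flagged as
#'   having produced no pellet (and is excluded downstream).
#' @param seed integer RNG seed.
#' @return A [TransitScenario-class] object.
#' @export
TransitScenario <- function(nPerGroup = 8,
                            meanSitt = c(WT = 108.6),
                            meanCaecalDwell = c(WT = 21.4),
                            meanCtt = c(WT = 22.86),
                            dispersion = 10,
                            pelletFailureProbability = 0,
                            seed) {
  if (missing(seed)) stop("a seed is required for every scenario")
  new("TransitScenario", nPerGroup = as.integer(nPerGroup),
      meanSitt = meanSitt, meanCaecalDwell = meanCaecalDwell,
      meanCtt = meanCtt, dispersion = as.numeric(dispersion),
      pelletFailureProbability = as.numeric(pelletFailureProbability),
      seed = as.integer(seed))
}

#' Construct a LengthScenario
#'
#' @param nPerGroup animals per group.
#' @param relaxedLengthMean fully relaxed small-intestinal length, cm.
#' @param toneShortening named numeric, cm of tone-induced shortening per
#'   group.
#' @param nicardipineResidualTone residual shortening under the
#'   relaxant, cm.
#' @param sd between-animal SD, cm.
#' @param seed integer RNG seed.
#' @return A [LengthScenario-class] object.
#' @export
LengthScenario <- function(nPerGroup = 21, relaxedLengthMean = 36.9,
                           toneShortening = c(WT = 3.7, Mut = 2.3),
                           nicardipineResidualTone = 0, sd = 2,
                           seed) {
  if (missing(seed)) stop("a seed is required for every scenario")
  new("LengthScenario", nPerGroup = as.integer(nPerGroup),
      relaxedLengthMean = as.numeric(relaxedLengthMean),
      toneShortening = toneShortening,
      nicardipineResidualTone = as.numeric(nicardipineResidualTone),
      sd = as.numeric(sd), seed = as.integer(seed))
}
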