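# Colonic stage: the event machinery applied to colonic maps. CMMCs are
# the colonic analogue of PCCs (same >50% extent criterion); short anal
# contractions are the sub-half-length events confined to the distal
# colon.

#' Short anal contractions and their share of total contractions
#'
#' A short anal contraction extends less than half the colon segment,
#' is confined to the anal half, and reaches the anal-most 10\% of the
#' segment ("appearing in the distal region"). The short fraction is the
#' percentage of total contractions (short anal + CMMC) that are short;
#' with no contraction at all it is undefined (NA, flagged), not zero.
#'
#' @param events classified events from [classifyEvents()] (or raw
#'   [extractEvents()] output; the PCC criterion is then applied with
#'   \code{r2Min}).
#' @param segmentLength colon segment length, mm.
#' @param analContactFraction anal-most fraction the footprint must
#'   reach (default 0.1).
#' @param r2Min minimum leading-edge R^2 for the CMMC criterion.
#' @return list with \code{count} (short anal contractions),
#'   \code{cmmc} (CMMC count), \code{fraction} (percent short of total,
#'   NA when undefined) and \code{defined} (logical).
#' @export
shortAnalContractions <- function(events, segmentLength,
                                  analContactFraction = 0.1,
                                  r2Min = 0.5) {
  if (segmentLength <= 0) stop("segmentLength must be > 0")
  if (!nrow(events))
    return(list(count = 0L, cmmc = 0L, fraction = NA_real_,
                defined = FALSE))
  half <- segmentLength / 2
  analZone <- (1 - analContactFraction) * segmentLength
  short <- events$extent_fraction < 0.5 &
    events$pos_min >= half &
    events$pos_max >= analZone
  cmmc <- isPcc(events, r2Min)
  nShort <- sum(short); nCmmc <- sum(cmmc & !short)
  total <- nShort + nCmmc
  list(count = nShort, cmmc = nCmmc,
       fraction = if (total > 0) 100 * nShort / total else NA_real_,
       defined = total > 0)
}

#' Colonic motility summary of a spatiotemporal map
#'
#' Runs constriction detection on a colonic map and summarizes it:
#' CMMC count in the window (events meeting the propagating criterion),
#' mean CMMC spatial extent, mid-colon resting diameter, and short anal
#' contractions with their percentage of total contractions.
#'
#' @param map a colonic [SpatioTemporalMap-class] (oral end at row 1).
#' @param window analysis window, s (default 900).
#' @param depthThreshold constriction threshold for
#'   [constrictionMask()].
#' @param minArea minimum component area for [extractEvents()].
#' @param r2Min minimum leading-edge R^2 for the CMMC criterion.
#' @return A [ColonSummary-class].
#' @examples
#' sc <- MotilityScenario(segmentLength = 70, restingDiameter = 3,
#'   events = eventSpec(onset_time = c(100, 400), origin_position = 0,
#'     extent_fraction = 1, velocity = 0.4, dwell = 25,
#'     depth_fraction = 0.5), seed = 3)
#' cmmcMetrics(simulateMap(sc)$map)
#' @export
cmmcMetrics <- function(map, window = 900, depthThreshold = 0.5,
                        minArea = 10L, r2Min = 0.5) {
  stopifnot(is(map, "SpatioTemporalMap"))
  mask <- constrictionMask(map, depthThreshold)
  events <- extractEvents(mask, map, minArea)
  events <- classifyEvents(events, segmentLength(map), r2Min = r2Min)
  inWin <- events[nrow(events) > 0 & events$onset >= 0 &
                  events$onset <= window, , drop = FALSE]
  sac <- shortAnalContractions(inWin, segmentLength(map), r2Min = r2Min)
  cmmcExtent <- inWin$spatial_extent[isPcc(inWin, r2Min)]
  mid <- widthTrace(map, segmentLength(map) / 2)
  new("ColonSummary",
      cmmcPer15min = sac$cmmc,
      cmmcLength = if (length(cmmcExtent)) mean(cmmcExtent) else NA_real_,
      restingDiameter = restingDiameter(mid),
      shortAnalPer15min = sac$count,
      shortFraction = sac$fraction)
}
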