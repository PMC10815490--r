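# PCC parameter set: frequency, quiescence, regional duration, width
# traces with their diameter envelope, intra-PCC (slow wave) frequency,
# and velocity summaries.

#' Number of PCCs in an analysis window
#'
#' Counts events that satisfy the PCC criterion (extent fraction above
#' one half with a consistent direction) and whose onset falls within
#' the analysis window. The window defaults to 15 min, the standard
#' per-recording analysis epoch.
#'
#' @param events data.frame from [extractEvents()] (classified or not).
#' @param window window length, s (> 0).
#' @param r2Min minimum leading-edge R^2 when events are unclassified.
#' @return integer count.
#' @export
pccFrequency <- function(events, window = 900, r2Min = 0.5) {
  if (window <= 0) stop("window must be > 0")
  if (!nrow(events)) return(0L)
  sum(isPcc(events, r2Min) & events$onset >= 0 & events$onset <= window)
}

#' Quiescent periods between successive PCCs
#'
#' The quiescence of a recording is the set of rest intervals between
#' the end of one PCC and the onset of the next, over consecutive PCC
#' pairs inside the window. Edge intervals (before the first or after
#' the last PCC) are not gaps; overlapping PCCs contribute a gap of 0.
#'
#' @inheritParams pccFrequency
#' @return list with \code{gaps} (numeric vector, s), \code{mean}
#'   (\code{NA} when fewer than two PCCs are present, with
#'   \code{defined = FALSE}) and \code{defined} (logical flag).
#' @export
quiescence <- function(events, window = 900, r2Min = 0.5) {
  if (window <= 0) stop("window must be > 0")
  keep <- nrow(events) > 0 & isPcc(events, r2Min)
  pcc <- events[keep & events$onset >= 0 & events$onset <= window, ,
                drop = FALSE]
  if (nrow(pcc) < 2L)
    return(list(gaps = numeric(), mean = NA_real_, defined = FALSE))
  pcc <- pcc[order(pcc$onset), ]
  gaps <- pmax(0, pcc$onset[-1] - pcc$end[-nrow(pcc)])
  list(gaps = gaps, mean = mean(gaps), defined = TRUE)
}

# Cross-section fractions: proximal / mid / distal sampling points along
# the segment. The heatmap arrows in the original protocol carry no
# stated fractions; quarter points are used and are configurable.
defaultRegionFractions <- c(proximal = 0.25, mid = 0.5, distal = 0.75)

#' Duration of one event at a regional cross-section
#'
#' The event's duration at a region is the time between the first and
#' last footprint sample at the cross-section column nearest to the
#' region's position (25\%, 50\%, 75\% of segment length for proximal,
#' mid, distal by default); 0 when the event never reaches that column.
#'
#' @param event a single-row data.frame from [extractEvents()].
#' @param map the [SpatioTemporalMap-class] the event came from.
#' @param region \code{"proximal"}, \code{"mid"} or \code{"distal"}.
#' @param regionFractions named fractions of segment length locating the
#'   three cross-sections.
#' @return duration in seconds.
#' @export
durationAt <- function(event, map, region = c("proximal", "mid", "distal"),
                       regionFractions = defaultRegionFractions) {
  region <- match.arg(region)
  stopifnot(is(map, "SpatioTemporalMap"), nrow(event) == 1L)
  target <- regionFractions[[region]] * segmentLength(map)
  col <- positions(map)[which.min(abs(positions(map) - target))]
  fp <- event$footprint[[1]]
  at <- fp$time[abs(fp$position - col) < spatialStep(map) / 2]
  if (!length(at)) return(0)
  max(at) - min(at)
}

#' Gut-width trace at a fixed position
#'
#' Extracts diameter against time at the map row nearest to
#' \code{position}, with the diameter envelope (resting = upper
#' quantile, constricted = lower quantile) attached.
#'
#' @param map a [SpatioTemporalMap-class].
#' @param position mm from the oral end; must lie within the segment.
#' @param hiQuantile,loQuantile envelope quantiles (defaults 0.95 /
#'   0.05).
#' @return A [WidthTrace-class].
#' @export
widthTrace <- function(map, position, hiQuantile = 0.95,
                       loQuantile = 0.05) {
  stopifnot(is(map, "SpatioTemporalMap"))
  if (position < 0 || position > segmentLength(map))
    stop("position ", position, " mm lies outside the segment [0, ",
         segmentLength(map), "] mm")
  i <- which.min(abs(positions(map) - position))
  values <- diameterMatrix(map)[i, ]
  env <- envelopeQuantiles(values, hiQuantile, loQuantile)
  new("WidthTrace", position = positions(map)[i],
      times = timePoints(map), values = unname(values),
      restingDiameter = env[["resting"]],
      constrictedDiameter = env[["constricted"]])
}

#' Resting and constricted diameter of a width trace
#'
#' The resting (maximum) and constricted (minimum) diameters of a trace
#' are its upper and lower envelope, taken as quantiles so that the
#' estimate is robust to the number of contraction events in the window.
#'
#' @param trace a [WidthTrace-class] or numeric vector of diameters.
#' @param hiQuantile,loQuantile quantiles with
#'   \code{0 < loQuantile < hiQuantile < 1}.
#' @return named numeric \code{c(resting =, constricted =)}, mm.
#' @examples
#' restingConstricted(c(rep(4.7, 50), rep(3.9, 50)))
#' @export
restingConstricted <- function(trace, hiQuantile = 0.95,
                               loQuantile = 0.05) {
  if (!(loQuantile > 0 && loQuantile < hiQuantile && hiQuantile < 1))
    stop("quantiles must satisfy 0 < loQuantile < hiQuantile < 1")
  values <- if (is(trace, "WidthTrace")) traceValues(trace) else trace
  envelopeQuantiles(values, hiQuantile, loQuantile)
}

#' Dominant intra-PCC (slow wave) frequency of a width trace
#'
#' Computes a mean-subtracted, Hann-windowed periodogram of the trace
#' and reports the dominant frequency within a search band covering
#' physiological smooth-muscle slow-wave rates. The peak of this
#' spectrum is the most common oscillation frequency between individual
#' contractions within contractile complexes.
#'
#' @param trace a [WidthTrace-class], or a numeric vector with
#'   \code{sampleInterval} supplied.
#' @param band two-element numeric search band (lo, hi), s^-1; default
#'   (0.2, 1.5).
#' @param sampleInterval seconds between samples (only for numeric
#'   traces).
#' @return A [Spectrum-class]; \code{dominantFrequency(x)} gives the
#'   peak and \code{spectralResolution(x)} the bin width.
#' @details The trace must be long enough to resolve the lower band edge
#'   (duration of at least two periods of \code{band[1]}). A constant
#'   trace has no oscillatory component and is an error.
#' @examples
#' t <- seq(0, 900, by = 0.2)
#' sp <- intraPccFrequency(4 + 0.3 * sin(2 * pi * 0.6 * t),
#'                         sampleInterval = 0.2)
#' dominantFrequency(sp)
#' @export
intraPccFrequency <- function(trace, band = c(0.2, 1.5),
                              sampleInterval = NULL) {
  if (is(trace, "WidthTrace")) {
    values <- traceValues(trace)
    dt <- diff(traceTimes(trace)[1:2])
  } else {
    if (is.null(sampleInterval))
      stop("sampleInterval is required for a numeric trace")
    values <- trace
    dt <- sampleInterval
  }
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2])
    stop("band must be (lo, hi) with 0 < lo < hi")
  n <- length(values)
  if (stats::sd(values) == 0)
    stop("no oscillatory component: trace is constant")
  if ((n - 1) * dt < 2 / band[1])
    stop("trace too short to resolve ", band[1], " 1/s (need >= ",
         2 / band[1], " s)")
  hann <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  x <- (values - mean(values)) * hann
  p <- Mod(stats::fft(x))^2
  k <- seq(0, floor(n / 2))
  freqs <- k / (n * dt)
  power <- p[k + 1]
  inBand <- freqs >= band[1] & freqs <= band[2]
  if (!any(inBand))
    stop("no spectral bins fall inside the search band")
  dom <- freqs[inBand][which.max(power[inBand])]
  new("Spectrum", frequencies = freqs, power = power,
      dominantFrequency = dom, searchBand = as.numeric(band),
      resolution = 1 / (n * dt))
}

#' Mean signed PCC velocity
#'
#' Averages the signed leading-edge velocities over PCCs - the sign (and
#' hence direction) is preserved, so equal and opposite velocities
#' average to zero. The \code{"subsample6"} mode mirrors the practice of
#' averaging 6 randomly selected contractions per preparation and
#' requires a seed.
#'
#' @param events data.frame from [extractEvents()].
#' @param mode \code{"all"} (default) or \code{"subsample6"}.
#' @param seed RNG seed, required for \code{"subsample6"}.
#' @param r2Min minimum leading-edge R^2 when events are unclassified.
#' @return mean velocity, mm/s (NA when no PCC qualifies in
#'   \code{"all"} mode).
#' @export
velocitySummary <- function(events, mode = c("all", "subsample6"),
                            seed = NULL, r2Min = 0.5) {
  mode <- match.arg(mode)
  v <- events$velocity[nrow(events) > 0 & isPcc(events, r2Min)]
  if (mode == "all") {
    if (!length(v)) return(NA_real_)
    return(mean(v))
  }
  if (length(v) < 6L)
    stop("subsample6 requires at least 6 PCCs (have ", length(v), ")")
  if (is.null(seed)) stop("subsample6 requires a seed")
  mean(withSeed(seed, sample(v, 6L)))
}
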