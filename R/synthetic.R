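# Synthetic-data generators: spatiotemporal maps with scheduled
# propagating constrictions, rendered frame stacks, transit cohorts on a
# radiographic observation grid, and paired gut-length cohorts. All
# generators are driven by explicit scenario seeds and are bit-for-bit
# reproducible.

# Travelling constriction depth (mm) contributed by one scheduled event,
# evaluated on the (position, time) grid. The constriction at a fixed
# position is a raised-cosine pulse of base width 2*dwell (full width at
# half depth = dwell); the pulse centre sweeps along the segment at the
# scheduled velocity. Scheduled onset_time is the arrival of the
# half-depth front at origin_position, so threshold-based detection at
# half depth recovers scheduled onsets, ends and dwell durations.
eventDepthField <- function(ev, pos, tim, segmentLength, restingDiameter) {
  v <- ev$velocity
  extent <- ev$extent_fraction * segmentLength
  span <- if (v > 0) c(ev$origin_position, ev$origin_position + extent)
          else c(ev$origin_position - extent, ev$origin_position)
  inSpan <- pos >= span[1] - 1e-9 & pos <= span[2] + 1e-9
  depth <- matrix(0, length(pos), length(tim))
  if (!any(inSpan)) return(depth)
  # base-support start of the pulse at each in-span position
  t0 <- ev$onset_time + (pos[inSpan] - ev$origin_position) / v - ev$dwell / 2
  u <- outer(-t0, tim, `+`)                    # time since base start
  w <- 0.5 * (1 - cos(pi * u / ev$dwell))
  w[u < 0 | u > 2 * ev$dwell] <- 0
  depth[inSpan, ] <- ev$depth_fraction * restingDiameter * w
  depth
}

#' Simulate a spatiotemporal diameter map with known ground truth
#'
#' Generates a diameter map as resting diameter, plus a sinusoidal
#' slow-wave component, minus the summed constriction profiles of the
#' scheduled events, plus additive Gaussian noise, clipped at zero.
#' The scheduled events are echoed back as ground truth so detection
#' stages can be validated against a known answer.
#'
#' @param scenario a [MotilityScenario-class].
#' @return A list with elements \code{map} (a
#'   [SpatioTemporalMap-class]) and \code{truth} (a data.frame with one
#'   row per scheduled event: \code{onset_time}, \code{end_time},
#'   \code{origin_position}, \code{extent} (mm), \code{extent_fraction},
#'   \code{velocity}, \code{dwell}, \code{depth_fraction}).
#' @details Scenarios whose events overlap so deeply that their summed
#'   constriction would exceed the resting diameter are rejected with a
#'   diagnostic: such schedules have no physical interpretation.
#'   Identical scenarios (including seed) give bit-identical maps.
#' @examples
#' sc <- MotilityScenario(events = eventSpec(onset_time = 100,
#'   origin_position = 0, extent_fraction = 1, velocity = 0.5,
#'   dwell = 30, depth_fraction = 0.5), seed = 42)
#' sim <- simulateMap(sc)
#' sim$map
#' sim$truth
#' @export
simulateMap <- function(scenario) {
  stopifnot(is(scenario, "MotilityScenario"))
  validObject(scenario)
  pos <- seq(0, scenario@segmentLength, by = scenario@spatialStep)
  tim <- seq(0, scenario@duration, by = scenario@temporalStep)
  base <- scenario@restingDiameter +
    scenario@slowWaveAmplitude * sin(2 * pi * scenario@slowWaveFrequency * tim)
  d <- matrix(base, nrow = length(pos), ncol = length(tim), byrow = TRUE)
  ev <- scenario@events
  if (nrow(ev)) {
    constriction <- matrix(0, length(pos), length(tim))
    for (k in seq_len(nrow(ev)))
      constriction <- constriction + eventDepthField(
        ev[k, ], pos, tim, scenario@segmentLength, scenario@restingDiameter)
    if (max(constriction) > scenario@restingDiameter + 1e-9)
      stop("invalid scenario: overlapping events sum to a constriction ",
           "deeper than the resting diameter (max summed depth ",
           signif(max(constriction), 4), " mm)")
    d <- d - constriction
  }
  if (scenario@noiseSd > 0) {
    d <- d + withSeed(scenario@seed,
                      matrix(stats::rnorm(length(d), 0, scenario@noiseSd),
                             nrow(d), ncol(d)))
  }
  d <- pmax(d, 0)
  truth <- if (nrow(ev)) {
    data.frame(
      onset_time = ev$onset_time,
      end_time = ev$onset_time +
        ev$extent_fraction * scenario@segmentLength / abs(ev$velocity) +
        ev$dwell,
      origin_position = ev$origin_position,
      extent = ev$extent_fraction * scenario@segmentLength,
      extent_fraction = ev$extent_fraction,
      velocity = ev$velocity,
      dwell = ev$dwell,
      depth_fraction = ev$depth_fraction)
  } else {
    data.frame(onset_time = numeric(), end_time = numeric(),
               origin_position = numeric(), extent = numeric(),
               extent_fraction = numeric(), velocity = numeric(),
               dwell = numeric(), depth_fraction = numeric())
  }
  list(map = SpatioTemporalMap(d, scenario@spatialStep,
                               scenario@temporalStep),
       truth = truth)
}

#' Render a spatiotemporal map as a synthetic video frame stack
#'
#' The inverse of the mapping stage: each map time sample becomes one
#' grayscale frame showing a bright tissue band on a dark background.
#' The band is centred vertically and the pixel height of each column is
#' \code{round(diameter / calibration)}, so silhouette thresholding and
#' per-column pixel counting recover the map up to quantization.
#'
#' @param map a [SpatioTemporalMap-class].
#' @param calibration mm per pixel (> 0).
#' @param fieldHeight frame height in pixels; must accommodate the
#'   largest diameter. Default: 25\% headroom above the largest band.
#' @param tissueIntensity,backgroundIntensity frame intensities in
#'   \[0, 1\]; background must be strictly darker than tissue.
#' @return A [FrameStack-class] with one frame per map time sample and
#'   one pixel column per map position; \code{frameRate = 1 /
#'   temporalStep(map)}.
#' @examples
#' sc <- MotilityScenario(duration = 10, events = eventSpec(), seed = 1)
#' stack <- renderFrames(simulateMap(sc)$map, calibration = 0.1)
#' stack
#' @export
renderFrames <- function(map, calibration, fieldHeight = NULL,
                         tissueIntensity = 0.8, backgroundIntensity = 0.1) {
  stopifnot(is(map, "SpatioTemporalMap"))
  if (!is.numeric(calibration) || length(calibration) != 1L ||
      calibration <= 0)
    stop("calibration must be a single positive number (mm/px)")
  if (backgroundIntensity >= tissueIntensity)
    stop("backgroundIntensity must be strictly below tissueIntensity")
  d <- diameterMatrix(map)
  maxPx <- max(round(d / calibration))
  if (is.null(fieldHeight)) fieldHeight <- ceiling(maxPx * 1.25)
  fieldHeight <- as.integer(fieldHeight)
  if (maxPx > fieldHeight)
    stop("fieldHeight (", fieldHeight, " px) cannot accommodate the ",
         "largest diameter (", maxPx, " px at ", calibration, " mm/px)")
  nt <- ncol(d); np <- nrow(d)
  frames <- array(backgroundIntensity, dim = c(nt, fieldHeight, np))
  heights <- round(d / calibration)           # np x nt, pixels
  for (j in seq_len(nt)) {
    h <- heights[, j]
    top <- floor((fieldHeight - h) / 2)
    frame <- matrix(backgroundIntensity, fieldHeight, np)
    for (i in seq_len(np)) {
      if (h[i] > 0) frame[(top[i] + 1):(top[i] + h[i]), i] <- tissueIntensity
    }
    frames[j, , ] <- frame
  }
  FrameStack(frames, frameRate = 1 / temporalStep(map),
             calibration = calibration,
             columnSpacing = spatialStep(map))
}

#' Simulate a radiographic transit cohort
#'
#' Draws true continuous arrival times of a contrast bolus at the
#' caecum, proximal colon and anus (first pellet) from per-group normal
#' distributions of the three transit components, then quantizes them
#' onto the serial-imaging observation grid (images every 5 min in the
#' first hour, every 10 min in the second, every 20 min afterwards): the
#' recorded time is the first imaging time at or after the true event.
#'
#' @param scenario a [TransitScenario-class].
#' @return data.frame with columns \code{animal_id}, \code{group},
#'   \code{gavage_time} (0), \code{caecum_arrival},
#'   \code{proximal_colon_arrival}, \code{first_pellet_time} (min, on
#'   the observation grid) and \code{pellet_produced} (logical; failed
#'   animals are flagged, not dropped). The unquantized times are
#'   attached as \code{attr(, "truth")}.
#' @seealso [observationGrid()], [transitTimes()]
#' @export
simulateTransitCohort <- function(scenario) {
  stopifnot(is(scenario, "TransitScenario"))
  validObject(scenario)
  groups <- names(scenario@meanSitt)
  withSeed(scenario@seed, {
    rows <- lapply(groups, function(g) {
      n <- scenario@nPerGroup
      draw <- function(mu) {
        x <- stats::rnorm(n, mu, scenario@dispersion)
        while (any(x <= 0))                 # transit components are positive
          x[x <= 0] <- stats::rnorm(sum(x <= 0), mu, scenario@dispersion)
        x
      }
      sitt <- draw(scenario@meanSitt[[g]])
      dwell <- draw(scenario@meanCaecalDwell[[g]])
      ctt <- draw(scenario@meanCtt[[g]])
      data.frame(animal_id = paste0(g, "_", seq_len(n)), group = g,
                 caecum = sitt, pcolon = sitt + dwell,
                 pellet = sitt + dwell + ctt,
                 pellet_produced = stats::runif(n) >=
                   scenario@pelletFailureProbability)
    })
    tru <- do.call(rbind, rows)
    grid <- observationGrid(20 * ceiling(max(tru$pellet) / 20) + 20)
    out <- data.frame(
      animal_id = tru$animal_id, group = tru$group, gavage_time = 0,
      caecum_arrival = snapToGrid(tru$caecum, grid),
      proximal_colon_arrival = snapToGrid(tru$pcolon, grid),
      first_pellet_time = snapToGrid(tru$pellet, grid),
      pellet_produced = tru$pellet_produced)
    attr(out, "truth") <- data.frame(
      animal_id = tru$animal_id, caecum_arrival = tru$caecum,
      proximal_colon_arrival = tru$pcolon, first_pellet_time = tru$pellet)
    out
  })
}

#' Simulate a paired gut-length cohort
#'
#' Each animal's small intestine is measured twice: under control
#' conditions (relaxed length shortened by group-specific smooth-muscle
#' tone) and after incubation in a muscle relaxant (only a residual tone
#' remains, common to groups). A per-animal normal deviate is shared
#' between the two measurements, making the design paired.
#'
#' @param scenario a [LengthScenario-class].
#' @return data.frame with columns \code{animal_id}, \code{group},
#'   \code{treatment} (\code{"control"} / \code{"nicardipine"}) and
#'   \code{length} (cm), two rows per animal.
#' @export
simulateLengthCohort <- function(scenario) {
  stopifnot(is(scenario, "LengthScenario"))
  validObject(scenario)
  groups <- names(scenario@toneShortening)
  withSeed(scenario@seed, {
    rows <- lapply(groups, function(g) {
      n <- scenario@nPerGroup
      animal <- stats::rnorm(n, 0, scenario@sd)
      ctrl <- scenario@relaxedLengthMean - scenario@toneShortening[[g]] + animal
      nica <- scenario@relaxedLengthMean - scenario@nicardipineResidualTone +
        animal
      id <- paste0(g, "_", seq_len(n))
      data.frame(animal_id = rep(id, 2), group = g,
                 treatment = rep(c("control", "nicardipine"), each = n),
                 length = c(ctrl, nica))
    })
    do.call(rbind, rows)
  })
}

#' Sample a study-regime motility scenario
#'
#' Draws a [MotilityScenario-class] whose parameters sit in the regimes
#' reported for ex vivo mouse preparations: 4-10 propagating complexes
#' per 15 min window, propagation speeds of 0.3-0.6 mm/s (anally
#' directed in the jejunum and colon, orally directed - negative - in
#' the ileum), slow-wave rates of 0.3-0.7 s^-1, and resting diameters
#' of roughly 3-5 mm. Colonic scenarios mix full-length complexes with
#' short anal contractions confined to the distal segment. Events share
#' a common depth and are spaced so their constrictions never overlap.
#'
#' @param seed integer seed; fully determines the scenario.
#' @param region \code{"jejunum"}, \code{"ileum"} or \code{"colon"}.
#' @param nEvents number of full-extent events; default drawn from
#'   4-10.
#' @param nShort number of short anal contractions (colon only).
#' @param noiseSd additive noise SD, mm (default 0: noiseless).
#' @return A [MotilityScenario-class].
#' @export
sampleStudyScenario <- function(seed, region = c("jejunum", "ileum",
                                                 "colon"),
                                nEvents = NULL, nShort = 0L,
                                noiseSd = 0) {
  region <- match.arg(region)
  withSeed(seed, {
    cfg <- switch(region,
      jejunum = list(L = 60, resting = 4.7, vsign = 1,
                     slow = stats::runif(1, 0.5, 0.7)),
      ileum   = list(L = 50, resting = 3.4, vsign = -1,
                     slow = stats::runif(1, 0.3, 0.6)),
      colon   = list(L = 70, resting = 3.0, vsign = 1,
                     slow = stats::runif(1, 0.3, 0.5)))
    if (is.null(nEvents)) nEvents <- sample(4:10, 1)
    speed <- stats::runif(1, 0.3, 0.6)
    dwell <- 20
    depth <- stats::runif(1, 0.45, 0.6)
    travel <- cfg$L / speed
    onsets <- seq(50, 880 - travel - dwell, length.out = nEvents)
    onsets <- onsets + stats::runif(nEvents, 0, min(8, diff(range(
      onsets)) / (4 * nEvents) + 1))
    origin <- if (cfg$vsign > 0) 0 else cfg$L
    ev <- eventSpec(onset_time = onsets, origin_position = origin,
                    extent_fraction = 1, velocity = cfg$vsign * speed,
                    dwell = dwell, depth_fraction = depth)
    if (nShort > 0L) {
      extf <- stats::runif(nShort, 0.25, 0.4)
      # shorts run through the distal segment midway between the distal
      # passes of consecutive full-length events, so footprints never
      # touch; candidates overflowing the recording are discarded
      sp <- mean(diff(onsets))
      candBase <- c(onsets[1] - sp / 2, onsets + sp / 2)
      picked <- 0L
      for (cb in candBase) {
        i <- picked + 1L
        if (i > nShort) break
        extMm <- extf[i] * cfg$L
        on <- cb + (cfg$L - extMm) / speed
        if (on - dwell / 2 < 5 ||
            on + extMm / speed + dwell > 895) next
        ev <- rbind(ev, eventSpec(
          onset_time = on, origin_position = cfg$L - extMm,
          extent_fraction = extf[i], velocity = speed, dwell = dwell,
          depth_fraction = depth))
        picked <- i
      }
      if (picked < nShort)
        stop("could not place ", nShort,
             " short contractions in this schedule")
    }
    MotilityScenario(segmentLength = cfg$L, duration = 900,
                     restingDiameter = cfg$resting,
                     slowWaveAmplitude = 0.2,
                     slowWaveFrequency = cfg$slow, events = ev,
                     noiseSd = noiseSd, spatialStep = 1,
                     temporalStep = 0.2,
                     seed = seed)
  })
}
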