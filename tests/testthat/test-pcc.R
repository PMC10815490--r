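# PCC detection and parameterization.

test_that("a constant map yields an all-false mask with a warning", {
  sim <- simulateMap(flatScenario(seed = 2))
  expect_warning(mask <- constrictionMask(sim$map), "zero dynamic range")
  expect_false(any(mask))
})

test_that("the constriction mask matches a deep event's footprint", {
  sc <- MotilityScenario(slowWaveAmplitude = 0, slowWaveFrequency = 0,
    duration = 300,
    events = eventSpec(onset_time = 50, origin_position = 0,
      extent_fraction = 1, velocity = 0.5, dwell = 30,
      depth_fraction = 0.5), seed = 14)
  sim <- simulateMap(sc)
  mask <- constrictionMask(sim$map)
  # true footprint: half-depth support, dwell wide at each position
  pos <- positions(sim$map); tim <- timePoints(sim$map)
  tOn <- outer(50 + pos / 0.5, rep(1, length(tim)))
  tMat <- matrix(tim, length(pos), length(tim), byrow = TRUE)
  truthFp <- tMat >= tOn & tMat <= tOn + 30
  jaccard <- sum(mask & truthFp) / sum(mask | truthFp)
  expect_gte(jaccard, 0.8)
})

test_that("raising the depth threshold shrinks the mask monotonically", {
  sc <- sampleStudyScenario(500, region = "jejunum")
  map <- simulateMap(sc)$map
  m1 <- constrictionMask(map, 0.3)
  m2 <- constrictionMask(map, 0.5)
  m3 <- constrictionMask(map, 0.8)
  expect_true(all(m2 <= m1))
  expect_true(all(m3 <= m2))
})

test_that("two disjoint diagonal bands become two events with correct signs", {
  sc <- MotilityScenario(slowWaveAmplitude = 0, slowWaveFrequency = 0,
    events = eventSpec(onset_time = c(100, 500),
      origin_position = c(0, 60), extent_fraction = 1,
      velocity = c(0.5, -0.5), dwell = 30, depth_fraction = 0.5),
    seed = 15)
  sim <- simulateMap(sc)
  ev <- extractEvents(constrictionMask(sim$map), sim$map, minArea = 50)
  expect_equal(nrow(ev), 2L)
  expect_gt(ev$velocity[1], 0)
  expect_lt(ev$velocity[2], 0)
  # slope recovery: 60 mm in 120 s -> 0.5 mm/s within 5%
  expect_equal(abs(ev$velocity), c(0.5, 0.5), tolerance = 0.05)
  expect_true(all(ev$fit_r2 > 0.99))
})

test_that("an advancing band's velocity is its slope", {
  # hand-built mask: front advances 30 mm in 60 s on a 60 mm segment
  d <- matrix(5, 61, 401)
  tim <- (0:400) * 0.2
  for (i in 1:31) {
    on <- (i - 1) / 0.5                  # 0.5 mm/s
    d[i, tim >= on & tim <= on + 10] <- 2
  }
  map <- SpatioTemporalMap(d, 1, 0.2)
  ev <- extractEvents(constrictionMask(map), map)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$velocity, 0.5, tolerance = 1e-6)
  expect_equal(ev$fit_r2, 1, tolerance = 1e-9)
  expect_equal(ev$spatial_extent, 30)
})

test_that("classification follows the extent and confinement rules", {
  L <- 60
  ev <- mkEvents(
    mkEvent(0, 40, 0, 24, L),       # 0.4 extent, oral half
    mkEvent(100, 200, 0, 60, L),    # full length
    mkEvent(300, 360, 10, 46, L),   # 0.6 extent, straddles midpoint
    mkEvent(400, 440, 36, 58, L),   # 0.37 extent, anal half
    mkEvent(500, 560, 0, 36, L, fit_r2 = 0.2))  # inconsistent direction
  cl <- classifyEvents(ev, L)
  expect_equal(as.character(cl$class),
               c("proximal_short", "full_length", "non_propagating",
                 "distal_short", "non_propagating"))
  expect_equal(cl$is_pcc, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  # the straddling 0.6-extent event is a PCC though neither short type
  expect_true(cl$is_pcc[3] && cl$class[3] == "non_propagating")
})

test_that("PCC frequency counts only qualifying events in the window", {
  L <- 60
  ev <- mkEvents(
    mkEvent(10, 130, 0, 60, L), mkEvent(150, 270, 0, 60, L),
    mkEvent(290, 410, 0, 60, L), mkEvent(430, 550, 0, 60, L),
    mkEvent(570, 690, 0, 60, L), mkEvent(710, 830, 0, 60, L),
    mkEvent(850, 880, 0, 18, L))        # extent 0.3: not a PCC
  expect_equal(pccFrequency(ev), 6L)
  expect_equal(pccFrequency(ev[0, ]), 0L)
  ev2 <- classifyEvents(ev, L)
  expect_equal(pccFrequency(ev2), 6L)
})

test_that("quiescence measures the gaps between consecutive PCCs", {
  L <- 60
  ev <- mkEvents(mkEvent(0, 30, 0, 60, L), mkEvent(70, 100, 0, 60, L),
                 mkEvent(140, 170, 0, 60, L))
  q <- quiescence(ev)
  expect_equal(q$gaps, c(40, 40))
  expect_equal(q$mean, 40)
  expect_true(q$defined)
  # a single PCC has no gaps; mean is flagged undefined
  q1 <- quiescence(ev[1, ])
  expect_equal(q1$gaps, numeric())
  expect_true(is.na(q1$mean) && !q1$defined)
  # overlapping PCCs floor at zero
  ov <- mkEvents(mkEvent(0, 100, 0, 60, L), mkEvent(80, 200, 0, 60, L))
  expect_equal(quiescence(ov)$gaps, 0)
})

test_that("scheduled gaps are recovered from detected events", {
  # 6 fast full-length events, spacing tuned for a 36 s mean gap
  ons <- seq(30, 30 + 5 * 126, by = 126)
  sc <- MotilityScenario(slowWaveAmplitude = 0, slowWaveFrequency = 0,
    temporalStep = 0.5,
    events = eventSpec(onset_time = ons, origin_position = 0,
      extent_fraction = 1, velocity = 1, dwell = 30,
      depth_fraction = 0.5), seed = 16)
  sim <- simulateMap(sc)
  ev <- extractEvents(constrictionMask(sim$map), sim$map, minArea = 50)
  q <- quiescence(ev)
  schedGap <- mean(ons[-1] - (ons[-6] + 60 / 1 + 30))
  expect_equal(schedGap, 36)
  expect_equal(q$mean, schedGap, tolerance = 2 * 0.5 / 36)
})

test_that("regional durations read the footprint at the cross-section", {
  L <- 60
  d <- matrix(5, 61, 301)
  d[26:36, 101:251] <- 2                 # mid block, 30 s at dt = 0.2
  map <- SpatioTemporalMap(d, 1, 0.2)
  ev <- extractEvents(constrictionMask(map), map)
  expect_equal(durationAt(ev[1, ], map, "mid"), 30)
  expect_equal(durationAt(ev[1, ], map, "distal"), 0)
  expect_equal(durationAt(ev[1, ], map, "proximal"), 0)
})

test_that("a scheduled dwell is recovered at the mid cross-section", {
  ons <- seq(30, 750, length.out = 6)
  sc <- MotilityScenario(slowWaveAmplitude = 0, slowWaveFrequency = 0,
    temporalStep = 0.5,
    events = eventSpec(onset_time = ons, origin_position = 0,
      extent_fraction = 1, velocity = 1, dwell = 60,
      depth_fraction = 0.5), seed = 17)
  sim <- simulateMap(sc)
  ev <- extractEvents(constrictionMask(sim$map), sim$map, minArea = 50)
  expect_equal(nrow(ev), 6L)
  durs <- vapply(seq_len(nrow(ev)), function(i)
    durationAt(ev[i, ], sim$map, "mid"), numeric(1))
  expect_true(all(abs(durs - 60) <= 2 * 0.5))
})

test_that("width trace envelope gives resting and constricted diameter", {
  rc <- restingConstricted(c(rep(4.7, 50), rep(3.9, 50)))
  expect_equal(unname(rc["resting"]), 4.7)
  expect_equal(unname(rc["constricted"]), 3.9)
  rcc <- restingConstricted(rep(3, 40))
  expect_equal(unname(rcc["resting"]), unname(rcc["constricted"]))
  expect_error(restingConstricted(1:10, hiQuantile = 0.4,
                                  loQuantile = 0.5), "quantiles")
})

test_that("width trace recovers a known envelope within the noise scale", {
  sc <- MotilityScenario(restingDiameter = 4.7, slowWaveAmplitude = 0,
    slowWaveFrequency = 0, noiseSd = 0.05,
    events = eventSpec(onset_time = seq(50, 700, length.out = 6),
      origin_position = 0, extent_fraction = 1, velocity = 1,
      dwell = 40, depth_fraction = 0.4), seed = 18)
  sim <- simulateMap(sc)
  tr <- widthTrace(sim$map, 30)
  expect_equal(restingDiameter(tr), 4.7, tolerance = 0.05 * 3)
  expect_equal(constrictedDiameter(tr), 4.7 * 0.6, tolerance = 0.15)
  expect_error(widthTrace(sim$map, 100), "outside the segment")
})

test_that("the periodogram finds a pure tone to within one bin", {
  t <- seq(0, 900, by = 0.2)
  sp <- intraPccFrequency(4 + 0.5 * sin(2 * pi * 0.6 * t),
                          sampleInterval = 0.2)
  expect_equal(spectralResolution(sp), 1 / (length(t) * 0.2))
  expect_lte(abs(dominantFrequency(sp) - 0.6), spectralResolution(sp))
})

test_that("the stronger of two tones dominates, matching a DFT oracle", {
  t <- seq(0, 900, by = 0.2)
  x <- sin(2 * pi * 0.4 * t) + 0.3 * sin(2 * pi * 0.9 * t)
  sp <- intraPccFrequency(x, sampleInterval = 0.2)
  expect_lte(abs(dominantFrequency(sp) - 0.4), spectralResolution(sp))
  # brute-force DFT oracle on the same windowed signal
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  y <- (x - mean(x)) * w
  freqs <- seq(0.2, 1.5, by = 1 / (n * 0.2))
  pw <- vapply(freqs, function(f) {
    k <- seq_len(n) - 1
    Mod(sum(y * exp(-2i * pi * f * k * 0.2)))^2
  }, numeric(1))
  expect_equal(dominantFrequency(sp), freqs[which.max(pw)],
               tolerance = 1 / (n * 0.2))
})

test_that("constant and too-short traces are rejected by the periodogram", {
  expect_error(intraPccFrequency(rep(4, 1000), sampleInterval = 0.2),
               "no oscillatory component")
  expect_error(intraPccFrequency(sin(1:20), sampleInterval = 0.2),
               "too short")
})

test_that("velocity summaries preserve sign and support subsampling", {
  L <- 60
  ev6 <- do.call(mkEvents, lapply(seq(0, 500, by = 100), function(t0)
    mkEvent(t0, t0 + 120, 0, 60, L, velocity = 0.5)))
  expect_equal(velocitySummary(ev6), 0.5)
  expect_equal(velocitySummary(ev6, mode = "subsample6", seed = 3), 0.5)
  # mixed signs average towards zero: sign is preserved, not magnitude
  evpm <- mkEvents(mkEvent(0, 120, 0, 60, L, velocity = 0.5),
                   mkEvent(200, 320, 60, 0, L, velocity = -0.5))
  expect_equal(velocitySummary(evpm), 0)
  # subsampling is seeded and reproducible, and guards its preconditions
  ev7 <- mkEvents(mkEvent(0, 120, 0, 60, L, velocity = 0.4),
                  mkEvent(130, 250, 0, 60, L, velocity = 0.5),
                  mkEvent(260, 380, 0, 60, L, velocity = 0.6),
                  mkEvent(390, 510, 0, 60, L, velocity = 0.3),
                  mkEvent(520, 640, 0, 60, L, velocity = 0.5),
                  mkEvent(650, 770, 0, 60, L, velocity = 0.7),
                  mkEvent(780, 890, 0, 60, L, velocity = 0.4))
  v1 <- velocitySummary(ev7, mode = "subsample6", seed = 9)
  v2 <- velocitySummary(ev7, mode = "subsample6", seed = 9)
  expect_identical(v1, v2)
  expect_error(velocitySummary(ev7[1:3, ], mode = "subsample6", seed = 1),
               "at least 6")
  expect_error(velocitySummary(ev7, mode = "subsample6"), "seed")
})

test_that("event counts never increase as the threshold deepens", {
  sc <- sampleStudyScenario(601, region = "ileum")
  map <- simulateMap(sc)$map
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9), function(th)
    nrow(extractEvents(constrictionMask(map, th), map, minArea = 50)),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("gaps plus PCC spans never exceed the window", {
  for (s in 1:5) {
    sc <- sampleStudyScenario(700 + s, region = "jejunum")
    sim <- simulateMap(sc)
    ev <- extractEvents(constrictionMask(sim$map), sim$map, minArea = 50)
    q <- quiescence(ev)
    midSpans <- sum(vapply(seq_len(nrow(ev)), function(i)
      durationAt(ev[i, ], sim$map, "mid"), numeric(1)))
    expect_lte(sum(q$gaps) + midSpans, 900 + 1e-9)
  }
})
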