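# Synthetic generators: maps, frames, transit and length cohorts.

test_that("an eventless noiseless scenario yields a constant map", {
  sim <- simulateMap(flatScenario(diameter = 4.7, seed = 3))
  expect_true(all(diameterMatrix(sim$map) == 4.7))
  expect_equal(nrow(sim$truth), 0L)
})

test_that("ground truth echoes the schedule exactly", {
  ons <- seq(60, 700, length.out = 6)
  sc <- MotilityScenario(events = eventSpec(onset_time = ons,
    origin_position = 0, extent_fraction = 1, velocity = 0.5,
    dwell = 30, depth_fraction = 0.5), seed = 9)
  tr <- simulateMap(sc)$truth
  expect_equal(nrow(tr), 6L)
  expect_equal(tr$onset_time, ons)
  expect_equal(tr$velocity, rep(0.5, 6))
  expect_equal(tr$extent, rep(60, 6))
  expect_equal(tr$end_time, ons + 60 / 0.5 + 30)
})

test_that("same scenario and seed give bit-identical maps", {
  sc <- function() MotilityScenario(events = eventSpec(onset_time = 100,
    origin_position = 0, extent_fraction = 1, velocity = 0.5,
    dwell = 30, depth_fraction = 0.5), noiseSd = 0.2, seed = 42L)
  m1 <- simulateMap(sc())$map
  m2 <- simulateMap(sc())$map
  expect_identical(diameterMatrix(m1), diameterMatrix(m2))
})

test_that("map values stay within the physical conservation bounds", {
  for (s in 1:5) {
    sc <- sampleStudyScenario(300 + s, region = "jejunum",
                              noiseSd = 0.1)
    sim <- simulateMap(sc)
    d <- diameterMatrix(sim$map)
    expect_true(all(d >= 0))
    expect_true(all(d <= sc@restingDiameter + sc@slowWaveAmplitude +
                      5 * sc@noiseSd))
  }
})

test_that("overlapping events exceeding resting depth reject the scenario", {
  sc <- MotilityScenario(events = eventSpec(onset_time = c(100, 100),
    origin_position = 0, extent_fraction = 1, velocity = 0.5,
    dwell = 30, depth_fraction = c(0.6, 0.6)), seed = 1)
  expect_error(simulateMap(sc), "overlapping events")
})

test_that("scenario invariants are enforced at construction", {
  expect_error(MotilityScenario(slowWaveAmplitude = 5,
                                restingDiameter = 4.7, seed = 1),
               "slowWaveAmplitude")
  expect_error(MotilityScenario(temporalStep = 2, slowWaveFrequency = 0.5,
                                seed = 1), "Nyquist")
  expect_error(MotilityScenario(events = eventSpec(onset_time = 10,
    origin_position = 0, extent_fraction = 1.5, velocity = 0.5,
    dwell = 20, depth_fraction = 0.5), seed = 1), "extent_fraction")
  expect_error(MotilityScenario(seed = 1, noiseSd = -1), "noiseSd")
})

test_that("rendered frames encode diameters as centred pixel bands", {
  sim <- simulateMap(flatScenario(diameter = 4.7, seed = 2, duration = 2))
  st <- renderFrames(sim$map, calibration = 0.1, fieldHeight = 60)
  f <- getFrame(st, 1)
  counts <- colSums(f > 0.5)
  expect_true(all(counts == 47))
  expect_equal(frameRate(st), 1 / temporalStep(sim$map))
  # background strictly below tissue
  expect_lt(min(f[f > min(f)]) - max(f[f == min(f)]), 1)
  expect_true(max(f) > min(f))
})

test_that("renderFrames rejects impossible calibrations and fields", {
  sim <- simulateMap(flatScenario(diameter = 4.7, seed = 2, duration = 2))
  expect_error(renderFrames(sim$map, calibration = -0.1), "calibration")
  expect_error(renderFrames(sim$map, calibration = 0.1, fieldHeight = 40),
               "fieldHeight")
})

test_that("transit cohort quantizes onto the observation grid", {
  sc <- TransitScenario(nPerGroup = 50, seed = 12)
  coh <- simulateTransitCohort(sc)
  tru <- attr(coh, "truth")
  grid <- observationGrid(max(coh$first_pellet_time) + 40)
  for (col in c("caecum_arrival", "proximal_colon_arrival",
                "first_pellet_time")) {
    expect_true(all(coh[[col]] %in% grid))
    gap <- coh[[col]] - tru[[col]]
    step <- diff(grid)[findInterval(tru[[col]], grid)]
    expect_true(all(gap >= 0))
    expect_true(all(gap < step))
  }
  # ordering invariant survives quantization
  expect_true(all(coh$caecum_arrival <= coh$proximal_colon_arrival))
  expect_true(all(coh$proximal_colon_arrival <= coh$first_pellet_time))
})

test_that("total pellet failure flags every record and transit excludes all", {
  sc <- TransitScenario(nPerGroup = 5, pelletFailureProbability = 1 - 1e-12,
                        seed = 4)
  coh <- simulateTransitCohort(sc)
  expect_true(all(!coh$pellet_produced))
  expect_message(tt <- transitTimes(coh), "excluded")
  expect_equal(nrow(tt), 0L)
  expect_equal(attr(tt, "n_excluded"), 5L)
})

test_that("length cohort reproduces forced means as sd -> 0", {
  coh <- simulateLengthCohort(LengthScenario(nPerGroup = 10,
    relaxedLengthMean = 36.9, toneShortening = c(WT = 3.7, Mut = 2.3),
    nicardipineResidualTone = 0, sd = 1e-12, seed = 5))
  m <- tapply(coh$length, list(coh$group, coh$treatment), mean)
  expect_equal(m["WT", "control"], 33.2, tolerance = 1e-9)
  expect_equal(m["Mut", "control"], 34.6, tolerance = 1e-9)
  expect_equal(m["WT", "nicardipine"], 36.9, tolerance = 1e-9)
  expect_equal(m["Mut", "nicardipine"], 36.9, tolerance = 1e-9)
  # zero tone + zero sd: all four cells identical
  coh0 <- simulateLengthCohort(LengthScenario(nPerGroup = 4,
    relaxedLengthMean = 36.9, toneShortening = c(WT = 0, Mut = 0),
    nicardipineResidualTone = 0, sd = 1e-12, seed = 5))
  expect_equal(max(coh0$length) - min(coh0$length), 0, tolerance = 1e-9)
})

test_that("cohort generators are reproducible under a fixed seed", {
  a <- simulateLengthCohort(LengthScenario(seed = 77))
  b <- simulateLengthCohort(LengthScenario(seed = 77))
  expect_identical(a, b)
  ta <- simulateTransitCohort(TransitScenario(seed = 77))
  tb <- simulateTransitCohort(TransitScenario(seed = 77))
  expect_identical(ta, tb)
})

test_that("scenario YAML round trip preserves every field", {
  sc <- sampleStudyScenario(8, region = "ileum")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeScenario(sc, path)
  sc2 <- readScenario(path)
  expect_equal(sc2@events, sc@events, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sc2@restingDiameter, sc@restingDiameter)
  expect_identical(sc2@seed, sc@seed)
  expect_identical(diameterMatrix(simulateMap(sc2)$map),
                   diameterMatrix(simulateMap(sc)$map))
})
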