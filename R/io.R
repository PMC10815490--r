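# Scenario files: structured YAML configs so simulated study conditions
# can be version-controlled and shared.

#' Write / read a scenario as a YAML config
#'
#' Scenarios serialize to YAML with a \code{type} field
#' (\code{motility}, \code{transit} or \code{length}) selecting the
#' class on read; a motility scenario's event schedule becomes a list of
#' per-event records. A write-read round trip reproduces the scenario.
#'
#' @param scenario a [MotilityScenario-class], [TransitScenario-class]
#'   or [LengthScenario-class].
#' @param path YAML file path.
#' @return \code{writeScenario} returns \code{path} invisibly;
#'   \code{readScenario} returns the scenario object.
#' @export
writeScenario <- function(scenario, path) {
  obj <- if (is(scenario, "MotilityScenario")) {
    list(type = "motility",
         segment_length = scenario@segmentLength,
         duration = scenario@duration,
         resting_diameter = scenario@restingDiameter,
         slow_wave_amplitude = scenario@slowWaveAmplitude,
         slow_wave_frequency = scenario@slowWaveFrequency,
         noise_sd = scenario@noiseSd,
         spatial_step = scenario@spatialStep,
         temporal_step = scenario@temporalStep,
         seed = scenario@seed,
         events = lapply(seq_len(nrow(scenario@events)), function(i)
           as.list(scenario@events[i, ])))
  } else if (is(scenario, "TransitScenario")) {
    list(type = "transit",
         n_per_group = scenario@nPerGroup,
         mean_sitt = as.list(scenario@meanSitt),
         mean_caecal_dwell = as.list(scenario@meanCaecalDwell),
         mean_ctt = as.list(scenario@meanCtt),
         dispersion = scenario@dispersion,
         pellet_failure_probability = scenario@pelletFailureProbability,
         seed = scenario@seed)
  } else if (is(scenario, "LengthScenario")) {
    list(type = "length",
         n_per_group = scenario@nPerGroup,
         relaxed_length_mean = scenario@relaxedLengthMean,
         tone_shortening = as.list(scenario@toneShortening),
         nicardipine_residual_tone = scenario@nicardipineResidualTone,
         sd = scenario@sd,
         seed = scenario@seed)
  } else stop("not a scenario object")
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname writeScenario
#' @export
readScenario <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$type))
    stop("scenario file has no 'type' field")
  switch(obj$type,
    motility = {
      events <- if (length(obj$events))
        do.call(rbind, lapply(obj$events, as.data.frame))
      else eventSpec()
      MotilityScenario(segmentLength = obj$segment_length,
                       duration = obj$duration,
                       restingDiameter = obj$resting_diameter,
                       slowWaveAmplitude = obj$slow_wave_amplitude,
                       slowWaveFrequency = obj$slow_wave_frequency,
                       events = events, noiseSd = obj$noise_sd,
                       spatialStep = obj$spatial_step,
                       temporalStep = obj$temporal_step,
                       seed = obj$seed)
    },
    transit = TransitScenario(
      nPerGroup = obj$n_per_group,
      meanSitt = unlist(obj$mean_sitt),
      meanCaecalDwell = unlist(obj$mean_caecal_dwell),
      meanCtt = unlist(obj$mean_ctt),
      dispersion = obj$dispersion,
      pelletFailureProbability = obj$pellet_failure_probability,
      seed = obj$seed),
    length = LengthScenario(
      nPerGroup = obj$n_per_group,
      relaxedLengthMean = obj$relaxed_length_mean,
      toneShortening = unlist(obj$tone_shortening),
      nicardipineResidualTone = obj$nicardipine_residual_tone,
      sd = obj$sd,
      seed = obj$seed),
    stop("unknown scenario type: ", obj$type))
}
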