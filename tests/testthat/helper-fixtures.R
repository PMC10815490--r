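# Shared fixtures: hand-constructed events and maps built in code.

# Build a single detected-style event row with a diagonal-band footprint
# running from (pos0, t0) to (pos1, t1). Used to exercise the
# classification / frequency / quiescence rules without running the
# detector.
mkEvent <- function(t0, t1, pos0, pos1, L, velocity = NULL,
                    fit_r2 = 0.99, nSamp = 50L) {
  tt <- seq(t0, t1, length.out = nSamp)
  pp <- seq(pos0, pos1, length.out = nSamp)
  if (is.null(velocity))
    velocity <- if (t1 > t0) (pos1 - pos0) / (t1 - t0) else NA_real_
  ev <- data.frame(event_id = 1L, onset = t0, end = t1,
                   pos_min = min(pos0, pos1), pos_max = max(pos0, pos1),
                   spatial_extent = abs(pos1 - pos0),
                   extent_fraction = abs(pos1 - pos0) / L,
                   velocity = velocity, fit_r2 = fit_r2,
                   n_samples = nSamp)
  ev$footprint <- list(data.frame(position = pp, time = tt))
  ev
}

mkEvents <- function(...) {
  out <- do.call(rbind, list(...))
  out$event_id <- seq_len(nrow(out))
  out
}

# Brute-force two-sided Mann-Whitney p-value by enumerating all
# assignments of the pooled ranks to group A.
mwExact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r <- rank(pooled)
  combos <- utils::combn(length(pooled), n)
  uAll <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  min(1, 2 * min(mean(uAll <= u), mean(uAll >= u)))
}

# A flat (eventless, noiseless) scenario: constant-diameter map.
flatScenario <- function(diameter = 4.7, seed = 1, duration = 60)
  MotilityScenario(restingDiameter = diameter, slowWaveAmplitude = 0,
                   slowWaveFrequency = 0, events = eventSpec(),
                   noiseSd = 0, duration = duration, seed = seed)
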