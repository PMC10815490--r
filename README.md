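# gutmotility

Quantitative analysis of gastrointestinal motility for R: from
organ-bath video of live gut segments to calibrated spatiotemporal
diameter maps, detected propagating contractile complexes (PCCs) and
colonic migrating motor complexes (CMMCs), in vivo transit times from
serial radiographs, and the statistics used to compare genotype and
drug groups. A fully seeded synthetic-data generator provides ground
truth for every stage, so the whole pipeline is testable without any
video data.

It is intended for gastrointestinal physiologists analysing ex vivo
motility recordings (mouse jejunum, ileum, colon and similar
preparations) and for methodologists who need a reproducible,
inspectable alternative to closed GUI tooling for the same
measurements.

## What it computes

**Maps.** Each video frame is thresholded into a tissue silhouette
(Otsu or fixed threshold, bright- or dark-tissue polarity) and the
diameter under each horizontal position is the count of silhouette
pixels times the mm/px calibration. Stacked over frames this gives the
diameter map `D(x, t)` (rows = positions, oral end first; columns =
time), with optional block-mean downsampling.

**Events.** Constricted samples are those below the per-position
resting diameter by more than a fraction (default 0.5) of the local
dynamic range, where resting/constricted diameters are the 0.95/0.05
quantiles of the width trace. Events are 8-connected components of
that mask. For each event: onset, end, spatial extent, and signed
velocity as the least-squares slope of position on time along the
leading edge (positive = oral to anal). An event with extent > 50% of
the segment and leading-edge R^2 >= 0.5 counts as a PCC (CMMC on
colonic maps); derived quantities include frequency per 15 min,
quiescence (gaps between consecutive PCCs), regional durations at the
25/50/75% cross-sections, resting/constricted diameter, short anal
contractions and their percentage of total colonic contractions, and
the intra-PCC (slow wave) frequency as the dominant peak of a
Hann-windowed periodogram in a 0.2-1.5 1/s band.

**Transit.** Arrival times scored on the radiographic schedule
(every 5 min in hour one, 10 min in hour two, 20 min after) yield
SITT (gavage to caecum), CTT (proximal colon to first pellet) and
WTT (gavage to pellet), with the pellet-failure exclusion rule and
`WTT >= SITT + CTT` guaranteed by the caecal dwell.

**Statistics.** Shapiro-Wilk screening with a D'Agostino-Pearson
fallback for tied samples; Student's t / Mann-Whitney U two-group
comparisons with an automatic route; Sidak and step-down Holm-Sidak
adjustment; two-way ANOVA (Type II) with Sidak-adjusted
within-treatment contrasts; mean +- SEM and percent-change summaries.

## Worked example

Simulate a 15 min jejunal recording with six scheduled full-length
PCCs (velocity 0.5 mm/s, dwell 30 s, depth half the resting diameter)
over a 0.6 1/s slow wave, then run the detection stack:

```r
library(gutmotility)

sc <- MotilityScenario(
  segmentLength = 60, duration = 900, restingDiameter = 4.7,
  slowWaveAmplitude = 0.25, slowWaveFrequency = 0.6,
  events = eventSpec(onset_time = seq(60, 760, length.out = 6),
                     origin_position = 0, extent_fraction = 1,
                     velocity = 0.5, dwell = 30, depth_fraction = 0.5),
  noiseSd = 0.1, seed = 42)
sim <- simulateMap(sc)
sim$map
#> SpatioTemporalMap: 61 positions x 4501 time samples
#>   segment 60.0 mm (step 1 mm), duration 900.0 s (step 0.2 s)
#>   diameter range 1.78-5.31 mm

mask   <- constrictionMask(sim$map, depthThreshold = 0.5)
events <- classifyEvents(extractEvents(mask, sim$map, minArea = 50),
                         segmentLength(sim$map))
events[, c("onset", "end", "extent_fraction", "velocity", "fit_r2", "class")]
#>   onset   end extent_fraction  velocity    fit_r2       class
#> 1  60.8 210.0               1 0.5036488 0.9993022 full_length
#> 2 200.8 350.0               1 0.5024179 0.9993731 full_length
#> 3 340.8 490.0               1 0.5035539 0.9993907 full_length
#> 4 480.8 630.2               1 0.5020560 0.9990781 full_length
#> 5 619.0 770.0               1 0.4981438 0.9996227 full_length
#> 6 760.8 900.0               1 0.5027428 0.9993868 full_length

pccFrequency(events)          # 6 PCCs in the 15 min window
#> [1] 6
velocitySummary(events)       # mean signed velocity, mm/s
#> [1] 0.5020939

tr <- widthTrace(sim$map, position = 30)   # mid-segment trace
restingConstricted(tr)        # envelope diameters, mm
#>     resting constricted
#>    4.992121    2.450628
dominantFrequency(intraPccFrequency(tr))   # slow wave, 1/s
#> [1] 0.5998667
```

All six scheduled events are recovered with the scheduled velocity
(within 1%), the diameter envelope matches the scenario (resting ~
4.7 + 0.25 mm slow-wave crest; constricted reflects the half-depth
events), and the slow-wave estimate lands within one spectral bin
(1/900 of a 1/s) of the scheduled 0.6. Group comparisons then go
through `compareTwo()`, `twoWayAnova()` and `percentChange()` - for
example `percentChange(152.9, 105.6)` returns `30.9`, the percent
reduction of a 152.9 min reference mean whole transit to a 105.6 min
comparison mean.

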