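---
title: "Quantifying gastrointestinal motility from spatiotemporal diameter maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gastrointestinal motility from spatiotemporal diameter maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutmotility)
```

## The measurement model

Ex vivo gut segments filmed from above in an organ bath appear as a
bright band of tissue whose local width is the gut diameter. The
mapping stage turns each video frame into a tissue silhouette by
intensity thresholding (Otsu's method per frame by default, with a
`tissue_bright`/`tissue_dark` polarity flag because rig lighting
varies), then counts silhouette pixels in each column and multiplies by
the calibration (mm per pixel). Stacking the per-frame profiles gives a
**spatiotemporal map** $D(x, t)$: diameter in mm indexed by position
along the segment (oral end at index 0) and time.

Two choices here deserve emphasis:

* **Counting, not extent.** The diameter under a column is the *count*
  of silhouette pixels, not the distance between the top and bottom
  edges. An interior hole in the silhouette therefore reduces the
  measured diameter. This is tested explicitly, so the behaviour is a
  contract, not an accident.
* **Block-mean downsampling.** When maps are downsampled in space or
  time, blocks are averaged rather than decimated, which acts as an
  anti-aliasing filter ahead of the spectral analysis below.

Calibration is supplied as a number (or derived by the user from a
known length in the field of view); there is no automatic ruler
detection. Camera orientation is declared with a `flip` flag since the
oral end may sit on either side of the frame.

## Contraction events

A **propagating contractile complex (PCC)** appears on a map as a
diagonal band of reduced diameter sweeping along the segment; its
colonic analogue is the **CMMC**. Detection proceeds in three steps:

1. **Constriction mask.** For each position, the resting and
   constricted diameters are the 0.95 and 0.05 quantiles of that
   position's width trace - a robust envelope that is insensitive to
   how many events happen to fall in the window ("average resting
   diameter" has no sharper published definition). A sample is marked
   constricted when the diameter drops below the resting value by more
   than half (`depthThreshold = 0.5`) of the local dynamic range.
2. **Components.** Events are 8-connected components of the mask with
   at least `minArea` samples (50 at the default 1 mm x 0.2 s grid;
   raise it for noisier recordings).
3. **Parameters.** Onset/end are the first/last footprint times;
   spatial extent is the span of occupied positions; the signed
   velocity is the least-squares slope of position on time over the
   *leading edge* (earliest occupied time at each position), which is
   how a front is read off a heatmap and is far less biased by
   footprint shape than a centroid fit. Positive velocity is
   oral-to-anal; retrograde (ileal) propagation is negative.

An event *counts as a PCC* when it spans more than 50% of the segment
with a consistent direction. "Consistent direction" is operationalized
as leading-edge $R^2 \ge 0.5$ (`r2Min`), since a propagating front is
approximately linear on these maps. The *class* labels are stricter:
`full_length` requires 90% extent (`fullLengthFraction = 0.9`), a
deliberately separate boundary because full-length contractions and the
>50% PCC criterion are distinct notions; sub-half-length events
confined to the oral or anal half are `proximal_short` or
`distal_short`. A 60%-extent event straddling the midpoint is a PCC
but none of these classes.

Derived parameters, all over a 15 min (900 s) analysis window to match
how per-window rates are conventionally reported:

* **Frequency**: PCC count per window.
* **Quiescence**: gaps between the end of one PCC and the onset of the
  next, over consecutive pairs; window edges are excluded and
  overlapping events floor at 0. Fewer than two PCCs leave the mean
  flagged undefined rather than 0.
* **Regional durations**: footprint dwell time at proximal/mid/distal
  cross-sections placed at 25% / 50% / 75% of segment length. The
  protocol this mirrors marks the three sites on the heatmap without
  stating fractions, so the quarter points are configurable.
* **Velocity summary**: mean signed velocity of all PCCs, or of 6
  seeded random picks (`subsample6`) for parity with the practice of
  averaging 6 randomly chosen contractions per preparation.

**Short anal contractions** (colon) extend less than 50% of the
segment, are confined to the anal half, *and* reach the anal-most 10%
of the segment. The contact requirement operationalizes "appearing in
the distal region": the region boundary is not defined in the source
protocols, and anal-half confinement alone would admit mid-colon
events. Short and CMMC are disjoint categories here; the short
fraction is 100 x short / (short + CMMC), undefined (flagged, not 0)
when nothing was detected.

## Intra-PCC (slow wave) frequency

The width trace at a fixed position oscillates within contractile
complexes at the smooth-muscle slow-wave rate set by the interstitial
cells of Cajal. `intraPccFrequency()` estimates it as the argmax of a
mean-subtracted, Hann-windowed periodogram within a search band of
0.2-1.5 s^-1, wide enough to bracket physiological jejunal and ileal
rates (0.3-0.7 s^-1). The spectral resolution 1/(N dt) is reported
alongside; at 900 s of trace it is about 0.0011 s^-1. A 15 min trace
sampled at 5 Hz resolves the band comfortably; constant traces are
rejected ("no oscillatory component") rather than returning a
meaningless argmax. The spectrum is computed on the whole window by
default; whether the original analyses restricted it to within-PCC
spans is not documented, and the per-event footprints returned by
`extractEvents()` let a user make that restriction themselves.

## In vivo transit

Serial radiographs after a contrast gavage are taken at t = 0, every
5 min in the first hour, every 10 min in the second, and every 20 min
afterwards (`observationGrid()`). A region arrival scored from such a
series is the *first image at or after* the true arrival
(right-quantization), which matches how a film series is read and
implies recorded group means exceed true means by less than the local
grid step - a property the tests verify on simulation. Transit times
are then SITT = gavage to caecum, CTT = proximal colon to first
contrast-containing pellet, WTT = gavage to pellet. The CTT clock
starts at the arrival of the marker *front* (the alternative, bulk
arrival, is not recoverable from scored records). Because the bolus
dwells in the caecum, WTT >= SITT + CTT with equality only at zero
dwell; the generator simulates the dwell explicitly since reported
group means imply a positive gap. Animals producing no
contrast-containing pellet are excluded with a diagnostic, and records
violating the arrival ordering are rejected at load, never silently
dropped.

## The statistical battery

* **Normality screening**: Shapiro-Wilk, except that samples containing
  repeated values (as grid-quantized transit times always do) fall back
  to the D'Agostino-Pearson omnibus K2 test, which tolerates ties;
  the route taken is reported. K2 is implemented from the standard
  skewness/kurtosis z-transformations and verified against an
  independent implementation.
* **Two-group comparisons**: Student's unpaired t-test when both
  samples pass the screen at alpha = 0.05, Mann-Whitney U otherwise;
  two-sided throughout. Mann-Whitney p-values are exact for
  min(n) <= 8 without ties and use the tie-corrected normal
  approximation otherwise (the original software's convention is not
  documented; this one is stated and tested). Two constant equal
  samples return p = 1 by convention, flagged.
* **Multiplicity**: Sidak, $1-(1-p)^m$, and step-down Holm-Sidak with
  a running maximum for monotonicity.
* **Two-way ANOVA** (genotype x treatment) with Type II sums of
  squares - the common choice for balanced or mildly unbalanced
  two-factor designs, recorded in the output metadata - plus
  Sidak-adjusted within-treatment genotype contrasts and Shapiro-Wilk
  residual normality.
* **Summaries**: mean +- SEM, and percent change
  $100(\bar{x}_{ref}-\bar{x}_{cmp})/\bar{x}_{ref}$ computed at full
  precision and rounded to one decimal, the conventional reporting
  precision; the sign is positive for a reduction.

## What the synthetic generator emulates

`simulateMap()` builds $D(x,t)$ as resting diameter + slow-wave
sinusoid - scheduled constrictions + truncated Gaussian noise, clipped
at zero. Each scheduled event is a **travelling raised-cosine pulse**:
at any position the constriction is a raised-cosine window whose *full
width at half depth* equals the scheduled `dwell`, and whose centre
sweeps at the scheduled velocity over the event's spatial span. The
scheduled onset is defined as the arrival of the half-depth front at
the origin. This convention is deliberate: a detector thresholding at
half the local dynamic range recovers scheduled onsets, ends and
dwells directly, so ground-truth comparisons are well-posed without
bias corrections, while the pulse remains smooth and monotone-fronted
(the property that makes least-squares velocity recovery work).
Schedules whose summed constriction would exceed the resting diameter
anywhere are rejected as unphysical. Noise is additive i.i.d. Gaussian
on diameter - the simplest model that exercises threshold robustness;
it does not emulate lighting drift, pinned-end artifacts or
longitudinal tissue motion, so passing tests show correct *map
arithmetic*, not robustness to those real-video effects.

`sampleStudyScenario()` draws scenarios in the reported physiological
regimes: 4-10 events per 15 min, speeds 0.3-0.6 mm/s (negative in the
ileum, where retrograde propagation is reported), slow waves
0.3-0.7 s^-1, resting diameters ~3-5 mm, 60-70 mm segments sampled at
1 mm and 0.2 s (0.2 s keeps the slow-wave band below Nyquist). Events
within a scenario share a common depth (0.45-0.6 of resting) so a
single half-range threshold sees them all; colonic scenarios add short
anal contractions threaded midway between the distal passes of
full-length events so footprints never merge. Transit cohorts draw the
three transit components from per-group normals (SITT 108.6 min,
caecal dwell 21.4 min, CTT 22.86 min for the reference wild-type
regime, dispersion 10 min) before grid quantization. Length cohorts
share one per-animal deviation between the paired control and relaxant
measurements; no published within-animal variance components exist, so
a single noise scale is exposed per scenario. Every generator takes a
mandatory scenario seed - seeds are data, not ambient state - and
identical scenarios are bit-identical.

## Validation problem sizes

The shipped tests and the acceptance script use: 20 seeded noiseless
900 s scenarios (alternating jejunal/ileal regimes) for count,
velocity and slow-wave recovery; 300 s scenarios at 0.1 mm/px for the
render-and-rebuild round trip and diameter-envelope agreement (one
pixel is the quantization bound); coarser 0.5 s sampling for
quiescence/duration recovery, whose tolerance is two temporal steps;
n = 200 per group for transit simulations; 1000 Gaussian-null
replicates for the two-group type-I calibration; and exhaustive rank
enumeration for Mann-Whitney up to n = 5 per group.

## Known limitations

* Animal-level published group means are not reproducible from raw
  data (none are deposited); synthetic recovery and closed-form worked
  examples are the validation surface.
* Whether pixel counting or edge-to-edge extent was used originally is
  documented only as the counting phrase quoted above; the count
  interpretation is taken literally.
* Drug effects (nitric oxide synthase inhibition, GABA-A antagonism)
  enter only as scenario parameters - there is no pharmacological or
  pacemaker-network model, and events are phenomenological.
* The quantile envelope makes resting/constricted estimates depend
  mildly on event load in the window; the 0.95/0.05 defaults trade a
  small bias for robustness and are configurable.
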