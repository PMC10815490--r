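Package: gutmotility
Title: Spatiotemporal Mapping and Quantification of Gastrointestinal Motility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying gastrointestinal motility from ex vivo
    organ-bath video recordings and in vivo transit records. Converts
    grayscale frame stacks of gut segments into calibrated spatiotemporal
    diameter maps by silhouette edge detection and per-column pixel
    counting, detects propagating contractile complexes (PCCs) and colonic
    migrating motor complexes (CMMCs) as connected space-time constriction
    regions, and parameterizes them (frequency, duration, spatial extent,
    signed propagation velocity, quiescence, resting and constricted
    diameter, and intra-complex oscillation frequency by windowed
    periodogram). Derives whole, small-intestinal and colonic transit
    times from serial radiographic observation schedules, and provides the
    accompanying statistical battery (normality screening with a
    tie-robust fallback, two-group tests, two-way ANOVA with Sidak
    contrasts, Sidak and Holm-Sidak adjustment, percent-change summaries).
    A fully seeded synthetic-data generator produces frame stacks, maps
    and cohorts with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    tiff,
    yaml,
    car,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
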