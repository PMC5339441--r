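Package: equirest
Title: Lying Behaviour of Group-Housed Horses from Leg-Worn Accelerometers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for recumbency (lying) behaviour of group-housed
    horses recorded with leg-worn single-axis accelerometers. Detects lying
    bouts from 1 Hz acceleration traces (threshold classification, moving-median
    majority smoothing, run-length segmentation, minimum-duration filter,
    pasture exclusion), joins video-derived bout annotations, and computes
    per-horse per-24 h outcome metrics by lying surface. Determines dominance
    rank from paired feeding encounters, dimensions littered lying areas
    according to Swiss welfare minima, and encodes the study's inference design:
    ordered-factor polynomial contrasts, log/logit outcome transformations,
    three-level nested random effects and marginality-respecting backward
    stepwise model reduction. A seeded synthetic-data generator reproduces the
    statistical structure of the study (day/night bout timing, space-allowance
    treatment effects, rank-dependent forced terminations) so every stage is
    testable without the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
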