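Package: TasteFace
Title: Facial-Landmark Geometry for Objective Palatability Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts per-frame facial-landmark streams recorded while
    children taste flavoured strips into twelve rescaled geometric facial
    measures (eyebrow elevation, tilt and shape, palpebral aperture, lip
    elevation and mouth-corner distance, left/right variants), summarises
    their per-video variability, relates that variability to taste identity
    and hedonic rating with nonparametric and ANOVA group tests, and ranks
    which measures best predict palatability with an extremely-randomised
    trees ensemble cross-checked against a principal-component ranking.
    Ships a synthetic landmark-stream generator with known ground truth
    (expression events, rigid head motion, estimator drop-out, hedonic
    cohort model) so the full pipeline is testable without any video data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ranger
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
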