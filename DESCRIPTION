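Package: lensuse
Title: Regions of Use of Progressive Power Lenses from Wearable Eye Tracking
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Locates the actually-used regions of a progressive power lens
    from wearable eye-tracker recordings. Each fixation's sight direction is
    intersected with the back surface of the lens and expressed relative to
    the fitting cross; regions of use are summarized by their center of mass,
    compared against theoretical zones derived from task geometry and
    per-eye vergence, and concordance statistics are reported. A seeded
    synthetic gaze simulator with configurable accuracy, precision and data
    loss makes the full pipeline testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
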