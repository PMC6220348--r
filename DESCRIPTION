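Package: vmradapt
Title: State-Space Simulation and Analysis of Visuomotor Rotation Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-by-trial state-space model of visuomotor rotation
    adaptation in which an internal estimate of the perturbation is updated
    by sensory prediction errors, together with a seeded synthetic cohort
    generator emulating a four-condition target-removal shooting experiment
    (explicit re-aiming strategy, implicit drift, delayed washout) and the
    accompanying statistical pipeline: trajectory-based shooting angles,
    signed angular errors, block-window summaries, single-exponential decay
    fits with participant bootstrap, one-way ANOVA with Tukey post-hoc, and
    end-of-adaptation to washout correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
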