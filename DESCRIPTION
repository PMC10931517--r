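Package: chronotell
Title: Circadian Phase and Clock-Dysfunction Estimation from Single
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the internal circadian phase of a single
    transcriptomic sample from a panel of rhythmic genes using a
    time-indexed probabilistic model: per-timepoint local principal
    component projections, multivariate normal fits, and periodic
    monotone cubic (PCHIP) interpolation of the mean and covariance over
    the day. Beyond the phase estimate it quantifies clock dysfunction
    through the maximum likelihood of the sample under the trained clock
    and the Theta metric derived from the likelihood-ratio function, and
    provides cohort-level analyses built on these: leave-one-out timing
    errors, circular timing displacements and molecular chronotype
    correction, phase-displacement regression of gene acrophases,
    Theta-stratified differential-expression resampling, and a
    timestamp-free timing-precision estimator. A synthetic cohort
    generator with clock-perturbation archetypes (coherent phase shift,
    amplitude collapse, gene knockout, frozen clock) supports validation
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
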