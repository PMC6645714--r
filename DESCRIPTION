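Package: saccRace
Title: Race-to-Threshold Modeling and Tachometric Analysis of Urgent Saccadic Choices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the compelled (urgent) antisaccade task with an
    accelerated race-to-threshold model in which two motor plans compete to
    trigger a saccade, and the detected cue first biases the race reflexively
    (halting of the plan away from the cue, transient acceleration of the plan
    toward it) before voluntary interpretation accelerates the correct plan
    and decelerates the incorrect one.  Provides tachometric-curve estimation
    (proportion correct as a function of raw processing time, in sliding
    bins), analytical dual-sigmoid fits and their characteristic features
    (vortex depth and time, edges, slopes, mean perceptual accuracy),
    percentile bootstrap confidence intervals, partial-correlation analyses
    of individual differences, synthetic experiment generation emulating a
    multi-participant study design, and fitting of the full model to
    reaction-time distributions and tachometric curves by shrinking-box
    random search.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
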