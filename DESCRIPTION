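Package: alphalat
Title: Posterior Alpha Lateralization Analysis and Decoding for Covert
    Spatial Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of posterior alpha-band (8-14 Hz)
    lateralization during covert visual spatial attention, as used in
    brain-computer interfacing. Provides a synthetic multichannel data
    generator with planted contralateral/ipsilateral alpha effects and 1/f
    background noise, a trial-rejection cascade (reaction time, gaze
    fixation, broadband power outliers), a synthetic planar-gradient
    transform, sliding-window Hanning-taper alpha power estimation,
    normalized lateralization indices with within-subject cluster-based
    sign-flip permutation inference over sensors and time, repeated-measures
    ANOVA utilities, and single-trial left/right hemifield decoding with
    leave-subject-out sensor selection and nested cross-validated linear
    support-vector classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
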