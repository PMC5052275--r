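Package: cuedtoj
Title: Race Models of Cued Temporal-Order Judgments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models temporal-order judgments (TOJs) in which a peripheral
    visual cue precedes one of the two targets. Stimulus encodings are
    exponential races in the tradition of the Theory of Visual Attention
    (TVA): the cued target (probe), the uncued target (reference), and the
    cue itself - which races to be miscategorized as the probe - compete
    for first encoding. Provides the closed-form "probe first" probability
    with cue censoring at probe onset and a neutral-rate regime for
    reference-before-cue presentations, a trial-level Monte-Carlo
    simulator, synthetic-experiment generators mirroring two cueing
    designs, hierarchical Bayesian estimation of subject- and group-level
    encoding rates by adaptive Markov chain Monte Carlo, nested model
    comparison by approximate leave-one-out cross-validation, and
    psychometric reporting (point of subjective simultaneity, difference
    limen, and the decomposition of curve shifts into cue-confusion versus
    rate-change contributions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    rlang,
    utils,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
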