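Package: ratcat
Title: Rat Visual Category Learning with the SUSTAIN Clustering Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for rodent touchscreen
    category-learning experiments in which rats classify Gabor gratings
    drawn from rotated bivariate-normal category distributions. Provides
    the normalized two-dimensional stimulus space and the four rotated
    category tasks (1D and 2D), an implementation of the SUSTAIN adaptive
    clustering network with selective attention, lesion-simulating model
    variants (static attention, trial-wise attention shuffling, raised
    cluster-recruitment threshold), model fitting to group-averaged
    learning curves with AIC comparison, trial-log dependent measures
    (session accuracy, perseverative errors, reaction-time outlier
    filtering, touch separation), a permutation-null perceptual-recency
    analysis, and a synthetic cohort generator that emulates a full
    touchscreen study design (8 subjects per group, 15 training sessions
    of 80 trials with correction loops, 5 testing sessions from expanded
    distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    lhs,
    patchwork,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
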