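Package: gazephase
Title: Time-Resolved Gaze-State Dynamics of Aesthetic Judgment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses the temporal unfolding of aesthetic judgment from eye-tracking
    data. Gaze scanpaths recorded during self-paced viewing of artworks are summarised
    as hidden Markov gaze states (two-dimensional Gaussian regions of interest with
    area and axis constraints), decoded per episode (posterior state probabilities and
    the Viterbi path), and aggregated into 3-s time bins over the first 30 s of
    viewing. Five distributional and dynamic indices per bin (normalised state
    entropy, maximum state probability, normalised effective number of states, total
    variation between consecutive bins, and the state-switching rate) are compared
    between high- and low-evaluation artwork groups with exact or tie-corrected
    Wilcoxon rank-sum tests, rank-biserial effect sizes, and Benjamini-Hochberg false
    discovery rate control. A seeded synthetic-study generator emulates the full study
    design (two artwork groups differing in rating level and in the onset of gaze
    convergence), and supplementary analyses cover depth-point fixation indices and
    decision-aligned gaze bias in two-alternative forced-choice preference trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
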