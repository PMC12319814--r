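Package: attnstates
Title: Trial-Level Reaction-Time Variability Models and Their BOLD Correlates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates Stop-Signal-Task behavior (adaptive stop-signal-delay
    staircase, race-model stop outcomes, a hidden two-state attentional
    process generating reaction times) together with parcellated BOLD
    time-series with known coupling to any reaction-time model series.
    Computes three trial-level attentional-state time-series from reaction
    times: the variance time course (smoothed absolute z-scores), the
    smoothed z-score, and the posterior state probability of a two-state
    Gaussian hidden Markov model fit by Baum-Welch. Relates each series to
    BOLD via amplitude-modulated and single-trial general linear models,
    combines runs with fixed effects, builds group maps, and compares maps
    across models with Dice overlap, network coverage, and spatial-null
    permutation correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
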