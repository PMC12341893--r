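Package: semspace
Title: Bayesian Multidimensional Scaling of Semantic Judgement Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mapping individual and group-level semantic spaces from
    forced-choice word judgement experiments. Builds balanced triadic
    odd-one-out and pairwise comparison designs over a four-class
    (concreteness x valence) word set, fits a Bayesian multidimensional
    scaling model to odd-one-out responses by Markov chain Monte Carlo
    (Minkowski distances in a latent 2D space, exponential-decay choice rule,
    per-participant response determinism), interprets the latent dimensions by
    regression on psycholinguistic word norms, quantifies spatial randomness
    of configurations against uniform nulls, scores pairwise judgements as
    relative scales with Kendall agreement and Crawford-Howell single-case
    statistics, and ships a synthetic-cohort generator emulating control-like
    and semantic-variant-like responders for end-to-end recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
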