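Package: dcemix
Title: Latent-Class Analysis of Discrete Choice Experiments with
    Partial-Profile Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing and analysing discrete choice (conjoint)
    experiments with partial-profile, no-level-overlap choice tasks.
    Generates randomized survey designs with fixed hold-out tasks, fits
    finite mixtures of conditional logit models (latent-class MNL) to
    effects-coded choice data by multi-start EM with Newton inner steps,
    computes information criteria and entropy-based class separation,
    bootstrap likelihood-difference tests and Wald tests, derives
    zero-centered part-worth utilities, attribute importance scores and
    posterior-weighted individual utilities, and predicts preference
    shares for profile scenarios by first-choice and randomized
    first choice simulation with hold-out validation. Includes a
    synthetic respondent generator reproducing the two-segment structure
    of a published survey of provider preferences for implementing
    evidence-based practices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
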