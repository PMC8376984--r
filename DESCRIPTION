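Package: pltricot
Title: Decentralized On-Farm Ranking Trials with Plackett-Luce Trees and a
    Genomic Prediction Benchmark
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of decentralized farmer-ranking (tricot) variety trials
    with the Plackett-Luce model and Plackett-Luce trees grown on agroclimatic
    covariates, optionally regularized by a marker-based additive relationship
    prior on log-worths. Includes agroclimatic index computation from daily
    weather over crop growth phases, blocked cross-validation with forward
    covariate selection scored by Akaike weights, a centralized GBLUP genomic
    prediction benchmark with station-trial BLUPs and heritability, Kendall-tau
    accuracy evaluation with square-root-sample-size season weighting, scenario
    extrapolation (win probabilities, reliability against check varieties,
    expected yield gain), and a synthetic-data generator that emulates the full
    two-arm trial structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
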