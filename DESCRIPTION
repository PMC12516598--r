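Package: melodiverge
Title: Melodic Sequence Alignment and Diversification Analysis for Folk Song Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the diversification of orally transmitted
    melodies. Melodies are coded as sequences over a 12-letter pitch-class
    alphabet, aligned pairwise with affine gap penalties to obtain percent
    identity and melodic distances, summarised within and between putative
    song groups (tune families) with the Brunner-Munzel rank test, projected
    into delta scores and Neighbor-Net split networks with SplitsTree4
    compatible NEXUS export, and modelled with pairwise-distance linear mixed
    models (random song-group intercept, Satterthwaite F tests, backward
    elimination) including simulation-based power analysis. A fully seeded
    synthetic-corpus generator emulating island archipelago folk-song
    transmission provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    phangorn,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
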