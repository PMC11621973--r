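Package: packsocial
Title: Social-System Analysis of Camera-Trap Observations of a Canid Group
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing coded camera-trap observations of a small
    social group of animals (developed for a golden jackal pack): observer
    reliability diagnostics (Cohen's kappa, autocorrelation of detection
    counts), dominance-hierarchy estimation via normalised David's scores
    built from aggression, submission and scent-marking win rules, and
    association-based social network analysis (simple-ratio or count
    association weights, eigenvector centrality, weighted modularity and
    fast-greedy community detection). Includes a synthetic event-log
    generator with a known latent hierarchy, planted association clusters,
    a composition timeline and identification noise, so every stage of the
    pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
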