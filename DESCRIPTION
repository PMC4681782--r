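Package: recallnet
Title: Attractor Neural-Network Modelling of Free Recall
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses a sparse Hopfield attractor network model of
    free recall from long-term memory. Memory items are random sparse binary
    patterns stored by a Hebbian covariance rule; retrieval is driven by
    sinusoidally oscillating feedback inhibition in the presence of neuronal
    noise, which moves the network between single-memory attractors and
    intersection states that act as stepping stones to new items. Provides the
    exact identical-population dimensionality reduction of the dynamics with a
    compiled low-rank integrator, the mean-field fixed-point theory of single-
    and intersection-attractor states with closed-form solutions and (kappa,
    phi) phase diagrams, and a tidy analysis layer for recall statistics:
    cumulative recall curves, inter-retrieval times, recall probability versus
    representation size, similarity-ranked transition statistics, and
    performance sweeps over temporal-contiguity coupling and noise amplitude.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
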