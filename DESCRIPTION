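Package: klinotaxis
Title: Connectome-Based Simulation of Klinotaxis and Random-Walk Behavior in C. elegans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates salt klinotaxis and random-walk locomotion of Caenorhabditis
    elegans with a 30-neuron graded-potential network on the worm's connectome
    scaffold. Sensory input comes from a conductance-based ASE model in which ASEL
    depolarizes in a stochastic all-or-none manner and ASER responds in a graded,
    saturating manner to concentration decreases. Network parameters are evolved by
    a genetic algorithm against a chemotaxis-index fitness; stochastic slowly-varying
    chemical synapse strengths ("liquid synapses") generate realistic random-walk
    statistics. Includes a behavioral-statistics suite (turning bias, bearing,
    gradient relationship curves, steering responses by locomotion phase,
    Kolmogorov-Smirnov turning-rate tests, lag correlations), simulated neuron
    ablation, and a random-connectome control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
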