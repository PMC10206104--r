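Package: bnmtune
Title: Whole-Brain Network Models with Tunable Excitation-Inhibition Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and fitting of dynamic mean-field whole-brain network
    models in which every long-range connection carries separately tunable
    excitatory-to-excitatory (long-range excitation) and
    excitatory-to-inhibitory (feedforward inhibition) coupling. Local
    inhibition is regulated by a homeostatic inhibitory-plasticity rule
    (feedback inhibition control) that drives excitatory populations to a
    4 Hz set point, and an online Hebbian-style learning rule adjusts
    pairwise E/I-ratios so that simulated functional connectivity matches an
    arbitrary target correlation matrix. The fitted large-scale models can
    drive a frontoparietal winner-take-all circuit for decision-making and
    working-memory experiments, linking network structure to speed-accuracy
    trade-offs. Includes a Balloon-Windkessel BOLD forward model, synthetic
    connectome/cohort generators, and tidy experiment surfaces.
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
    withr,
    ggplot2,
    generics,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    deSolve,
    optparse,
    yaml
Config/testthat/edition: 3
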