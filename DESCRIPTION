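Package: entropybathtub
Title: Driven Markov Jump Processes and the Entropy Bathtub Life Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator for driven continuous-time Markov jump processes on
    one-dimensional energy landscapes (chains and rings of potential wells),
    with full stochastic-thermodynamic accounting: Shannon system entropy,
    Schnakenberg entropy-production and entropy-export rates, probability
    currents, non-equilibrium steady-state (NESS) certification via the
    Kolmogorov cycle criterion, and the characteristic "entropy bathtub"
    life-cycle trajectory produced by rectangular or trapezoidal driving
    protocols with reversible (pulse) and irreversible (step) stressor
    perturbations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    pracma,
    stats,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
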